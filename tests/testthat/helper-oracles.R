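# Independent oracles used to check the coordinate-descent solver. FISTA
# (accelerated proximal gradient) minimises the same objective
#   ||y - X b||^2 + lambda ||b||_1
# by a completely different route, so agreement of the objectives is a
# genuine cross-check.

fista_lasso <- function(X, y, lambda, max_iter = 50000, tol = 1e-13) {
  p <- ncol(X)
  L <- 2 * max(eigen(crossprod(X), symmetric = TRUE,
                     only.values = TRUE)$values)
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  obj <- function(b) sum((y - X %*% b)^2) + lambda * sum(abs(b))
  b <- numeric(p)
  z <- b
  tk <- 1
  last <- obj(b)
  for (it in seq_len(max_iter)) {
    grad <- -2 * as.numeric(crossprod(X, y - X %*% z))
    b_new <- soft(z - grad / L, lambda / L)
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    z <- b_new + ((tk - 1) / tk_new) * (b_new - b)
    b <- b_new
    tk <- tk_new
    if (it %% 50 == 0) {
      cur <- obj(b)
      if (abs(last - cur) < tol * max(1, abs(cur))) break
      last <- cur
    }
  }
  list(beta = b, objective = obj(b))
}

# closed-form modularity Q = sum_i (e_ii - a_i^2) for a given membership
modularity_closed_form <- function(edge_from, edge_to, membership) {
  m <- length(edge_from)
  comms <- sort(unique(membership))
  e <- matrix(0, length(comms), length(comms),
              dimnames = list(comms, comms))
  for (k in seq_len(m)) {
    ci <- as.character(membership[[edge_from[k]]])
    cj <- as.character(membership[[edge_to[k]]])
    e[ci, cj] <- e[ci, cj] + 1 / (2 * m)
    e[cj, ci] <- e[cj, ci] + 1 / (2 * m)
  }
  sum(diag(e)) - sum(rowSums(e)^2)
}
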