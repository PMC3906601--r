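# synthetic multi-omics generator and its benchmark instruments

test_that("generation is a pure function of the configuration", {
  cfg <- sim_config(N = 50, J = c(CNA = 4, methylation = 20, miRNA = 8),
                    genes = 10, seed = 7)
  a <- simulate_multiomics(cfg)
  b <- simulate_multiomics(cfg)
  for (ty in names(a$dataset$blocks))
    expect_identical(a$dataset$blocks[[ty]]$values,
                     b$dataset$blocks[[ty]]$values)
  expect_identical(a$dataset$expression$values,
                   b$dataset$expression$values)
  expect_identical(a$truth$beta, b$truth$beta)
  # a different seed changes the data
  c2 <- simulate_multiomics(sim_config(N = 50,
                                       J = c(CNA = 4, methylation = 20,
                                             miRNA = 8),
                                       genes = 10, seed = 8))
  expect_false(identical(a$dataset$expression$values,
                         c2$dataset$expression$values))
})

test_that("marginals respect each feature type's family", {
  cfg <- sim_config(N = 120, J = c(CNA = 6, methylation = 30, miRNA = 10),
                    genes = 12, seed = 3)
  sim <- simulate_multiomics(cfg)
  cna <- sim$dataset$blocks$CNA$values
  expect_true(all(cna %in% c(-2, -1, 0, 1, 2)))
  met <- sim$dataset$blocks$methylation$values
  expect_true(all(met > 0 & met < 1))
  expect_true(all(is.finite(sim$dataset$blocks$miRNA$values)))
  # generated blocks survive normalization (no constant columns)
  expect_silent(normalize_dataset(sim$dataset))
  # infeasible sparsity is rejected
  expect_error(sim_config(J = c(CNA = 2, methylation = 30, miRNA = 10),
                          s = 3), "infeasible")
})

test_that("designated cross-type pairs achieve the requested correlation", {
  cfg <- sim_config(N = 500, J = c(CNA = 5, methylation = 60, miRNA = 30),
                    genes = 30, frac_null = 0, frac_multi = 0,
                    cross_type_rho = 0.9, seed = 11)
  sim <- simulate_multiomics(cfg)
  reg <- sim$truth$registry
  # methylation-causal features paired with miRNA partners: sample
  # correlation close to the latent 0.9 after the marginal transforms
  mm <- reg[reg$feature_type == "methylation" &
              reg$partner_type == "miRNA", ]
  expect_gt(nrow(mm), 2)
  X <- cbind(sim$dataset$blocks$methylation$values,
             sim$dataset$blocks$miRNA$values)
  cors <- mapply(function(a, b) cor(X[, a], X[, b]),
                 mm$feature_id, mm$partner_id)
  expect_true(all(cors > 0.85 & cors < 0.95))
})

test_that("a noiseless driven trait is recovered exactly by the lasso", {
  cfg <- sim_config(N = 100, J = c(CNA = 4, methylation = 20, miRNA = 8),
                    genes = 4, s = 2, noise_sd = 0, frac_null = 0,
                    frac_multi = 1, cross_type_rho = 0, seed = 5)
  sim <- simulate_multiomics(cfg)
  ds <- normalize_dataset(sim$dataset)
  X <- do.call(cbind, lapply(ds$blocks, function(b) {
    m <- b$values
    colnames(m) <- paste(b$type_label, colnames(m), sep = "|")
    m
  }))
  g <- sim$truth$roles$gene_id[1]
  y <- ds$expression$values[g, ]
  y <- y - mean(y)
  f <- lasso_fit(X, y, lambda = lambda_max(X, y) * 1e-4, tol = 1e-12)
  got <- names(coef(f))[abs(coef(f)) > 1e-6]
  truth_g <- sim$truth$beta[sim$truth$beta$gene_id == g, ]
  expect_setequal(got, paste(truth_g$feature_type, truth_g$feature_id,
                             sep = "|"))
})

test_that("trait variance decomposes into signal plus noise", {
  cfg <- sim_config(N = 2000, J = c(CNA = 4, methylation = 20, miRNA = 8),
                    genes = 6, s = 3, noise_sd = 1, frac_null = 0,
                    frac_multi = 1, cross_type_rho = 0, archetypes = FALSE,
                    seed = 9)
  sim <- simulate_multiomics(cfg)
  for (g in sim$truth$roles$gene_id) {
    b <- sim$truth$beta$beta[sim$truth$beta$gene_id == g]
    y <- sim$dataset$expression$values[g, ]
    # causal features are independent latents, z-scored: Sigma ~ I
    expect_equal(var(y), sum(b^2) + 1, tolerance = 0.12)
  }
})

test_that("recovery metrics honour their conventions", {
  cfg <- sim_config(N = 50, J = c(CNA = 4, methylation = 10, miRNA = 6),
                    genes = 3, s = 2, frac_null = 0, frac_multi = 0,
                    cross_type_rho = 0, seed = 2)
  sim <- simulate_multiomics(cfg)
  truth <- sim$truth
  # perfect recovery: feed the truth back in as a fit table
  perfect <- data.frame(truth$beta, p_value = 1e-6, lambda = 1,
                        accuracy = NA_real_)
  m <- recovery_metrics(perfect, truth)
  expect_equal(unname(m$overall[c("precision", "recall", "f1")]),
               c(1, 1, 1))
  expect_equal(unname(m$overall["rmse_support"]), 0)
  # empty selection: recall 0, precision undefined
  none <- perfect[0, ]
  m0 <- recovery_metrics(none, truth)
  expect_equal(unname(m0$overall["recall"]), 0)
  expect_true(is.na(m0$overall["precision"]))
})

test_that("benchmark rows carry coherent counts", {
  cfg <- sim_config(N = 60, J = c(CNA = 4, methylation = 16, miRNA = 6),
                    genes = 8, seed = 3)
  b <- spurious_benchmark(cfg, n_replicates = 2, seed = 5)
  expect_s3_class(b, "spurious_benchmark")
  expect_equal(nrow(b), 2L)
  expect_true(all(b$false_edges_integrative <= b$n_edges_integrative))
  expect_true(all(b$venn_all3_integrative >= 0))
  # deterministic given the master seed
  b2 <- spurious_benchmark(cfg, n_replicates = 2, seed = 5)
  expect_identical(as.data.frame(b), as.data.frame(b2))
})
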