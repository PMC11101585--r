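masked_toy_rows <- function(n = 400, miss = 0.2, seed = 1) {
  set.seed(seed)
  x <- sample(c("A", "B"), n, replace = TRUE)
  # z strongly tied to x: log-odds 2
  pz <- stats::plogis(-1 + 2 * (x == "B"))
  z <- ifelse(stats::runif(n) < pz, "B", "A")
  rows <- data.frame(person_id = paste0("P", seq_len(n)),
                     sex = sample(c("Female", "Male"), n, replace = TRUE),
                     ethnicity = "White", x = x, z = z, z_true = z,
                     stringsAsFactors = FALSE)
  rows$z[stats::runif(n) < miss] <- NA
  rows
}

test_that("zero missingness makes the module the identity", {
  rows <- masked_toy_rows(miss = 0)
  cfg <- impute_config(n_imputations = 3, n_iterations = 2, seed = 5,
                       variables = c("x", "z"))
  imp <- chained_imputation(rows, cfg)
  for (d in imp$imputations) expect_identical(d, rows)
  pooled <- pool_by_mode(imp)
  expect_identical(pooled$z, rows$z)
  expect_true(all(pooled$z_prov == "observed"))
})

test_that("mode pooling follows the stated tie-break and multiset rules", {
  rows <- data.frame(person_id = "P1", v = NA_character_)
  mk <- function(vals) lapply(vals, function(x) {
    d <- rows; d$v <- x; d
  })
  pool <- function(vals) {
    imp <- structure(list(imputations = mk(vals),
                          miss = matrix(TRUE, 1, 1,
                                        dimnames = list(NULL, "v")),
                          rows = rows), class = "its_imputations")
    pool_by_mode(imp)
  }
  expect_identical(pool(c("A", "A", "B"))$v, "A")     # majority
  expect_identical(pool(c("B", "B", "B"))$v, "B")     # unanimity
  expect_identical(pool(c("B", "A"))$v, "A")          # tie -> lowest code
  expect_identical(pool(c("A", "A", "B"))$v_prov, "imputed")
})

test_that("imputation is deterministic under a fixed seed and preserves observed cells", {
  rows <- masked_toy_rows(n = 250, seed = 3)
  cfg <- impute_config(n_imputations = 3, n_iterations = 2, seed = 11,
                       variables = c("x", "z"))
  a <- chained_imputation(rows, cfg)
  b <- chained_imputation(rows, cfg)
  expect_identical(a$imputations, b$imputations)
  obs_cells <- !is.na(rows$z)
  pooled <- pool_by_mode(a)
  expect_identical(pooled$z[obs_cells], rows$z[obs_cells])
  # every filled cell is one of its imputed values
  miss_cells <- which(is.na(rows$z))
  draws <- sapply(a$imputations, function(d) d$z[miss_cells])
  in_multiset <- vapply(seq_along(miss_cells), function(k)
    pooled$z[miss_cells[k]] %in% draws[k, ], TRUE)
  expect_true(all(in_multiset))
})

test_that("conditional imputation beats the marginal-mode baseline", {
  acc_mice <- acc_mode <- numeric(4)
  for (r in 1:4) {
    rows <- masked_toy_rows(n = 500, seed = 20 + r)
    cfg <- impute_config(n_imputations = 5, n_iterations = 3, seed = r,
                         variables = c("x", "z"))
    pooled <- pool_by_mode(chained_imputation(rows, cfg))
    cells <- is.na(rows$z)
    acc_mice[r] <- mean(pooled$z[cells] == rows$z_true[cells])
    marginal_mode <- names(which.max(table(rows$z)))
    acc_mode[r] <- mean(marginal_mode == rows$z_true[cells])
  }
  expect_gt(mean(acc_mice), mean(acc_mode))
})

test_that("degenerate inputs are rejected with clear errors", {
  rows <- data.frame(person_id = "P1", sex = "Female", ethnicity = "White",
                     z = NA_character_)
  expect_error(chained_imputation(rows, impute_config(variables = "z")),
               "100% missingness")
  expect_error(impute_config(n_imputations = 0), ">= 1")
  expect_error(pool_by_mode(list(data.frame(a = 1), data.frame(a = 1:2))),
               "shape mismatch")
})
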