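ctrl <- kader_control()
c_recs <- kader_records(c("C1", "C2", "C3", "C4"))
c_fits <- lapply(c_recs, agdf, control = ctrl)

test_that("proportional curves are explained perfectly by proportional covariates", {
  # the four uniform-onset populations differ only by a scale factor, so any
  # covariate proportional to that factor gives a perfect functional fit
  for (get in list(total_germination,
                   function(r) germination_index(r, 10))) {
    x <- vapply(c_recs, get, 0)
    m <- fosr(c_fits, x)
    expect_false(m$singular)
    expect_equal(m$r2_glob, 1, tolerance = 1e-8)
  }
  m_cgi <- fosr(c_fits, vapply(c_fits, cgi, 0), label = "CGI")
  expect_equal(m_cgi$r2_glob, 1, tolerance = 1e-8)
  # and the pointwise coefficient is 1 wherever the curves differ
  r2t <- r2_pointwise(m_cgi, seq(0.5, 9.5, by = 0.5))
  expect_true(all(r2t$r2[r2t$defined] > 1 - 1e-6))
})

test_that("constant covariates make the model singular with NA R-squared", {
  for (get in list(lt50, mean_germination_time, coefficient_of_velocity)) {
    x <- vapply(c_recs, get, 0)
    expect_lt(stats::var(x), 1e-12)
    m <- fosr(c_fits, x)
    expect_true(m$singular)
    expect_true(is.na(r2_global(m)))
  }
  expect_error(r2_pointwise(fosr(c_fits, rep(2, 4)), 1:9), "singular")
})

test_that("identical curves give an undefined R-squared (zero total variation)", {
  same <- lapply(1:3, function(i) c_fits[[1L]])
  m <- fosr(same, c(1, 2, 3))
  expect_false(m$singular)
  expect_true(is.na(m$r2_glob))
})

test_that("a zero slope function gives zero R-squared", {
  # covariate uncorrelated by symmetry with curves? construct directly:
  # regress distinct curves on a covariate orthogonal to their variation
  f1 <- c_fits[[1L]]; f2 <- c_fits[[4L]]
  m <- fosr(list(f1, f2, f1, f2), c(1, 1, 2, 2))
  expect_false(m$singular)
  expect_equal(m$r2_glob, 0, tolerance = 1e-10)
  r2t <- r2_pointwise(m, seq(1, 9, by = 1))
  expect_true(all(r2t$r2[r2t$defined] < 1e-10))
})

test_that("coefficient-space OLS minimises the integrated least-squares criterion", {
  spec <- knot_spec(c(0, 1), 1L)
  mk <- function(b) structure(list(coefficients = b, spec = spec),
                              class = "agdf")
  curves <- list(mk(c(0.1, 0.6)), mk(c(0.3, 0.5)), mk(c(0.5, 1.0)))
  x <- c(0, 1, 2)
  m <- fosr(curves, x)
  # independent route: minimise the integrated SSE over the 4 coefficient
  # entries of (beta0, beta1) with a fine-grid integral and Nelder-Mead
  g <- seq(0, 1, length.out = 2001L)
  B <- eval_basis(spec, g)
  Yg <- t(vapply(curves, function(f) drop(B %*% f$coefficients), numeric(length(g))))
  sse <- function(par) {
    beta <- matrix(par, 2L, 2L)
    Fg <- cbind(1, x) %*% beta %*% t(B)
    pracma::trapz(g, colSums((Yg - Fg)^2))
  }
  opt <- optim(rep(0, 4L), sse, control = list(maxit = 5000, reltol = 1e-14))
  expect_equal(as.numeric(m$coefficients), opt$par, tolerance = 1e-4)
})

test_that("global R-squared is invariant to covariate affine maps and curve permutation", {
  recs <- kader_records(c("B1", "B2", "B3", "B4", "E1", "E2"))
  fits <- lapply(recs, agdf, control = ctrl)
  x <- vapply(fits, cgi, 0)
  r2 <- fosr(fits, x)$r2_glob
  expect_equal(fosr(fits, 3 * x - 7)$r2_glob, r2, tolerance = 1e-10)
  expect_equal(fosr(fits, -0.5 * x)$r2_glob, r2, tolerance = 1e-10)
  perm <- c(4, 2, 6, 1, 3, 5)
  expect_equal(fosr(fits[perm], x[perm])$r2_glob, r2, tolerance = 1e-10)
})

test_that("global R-squared equals the integrated pointwise ratio", {
  recs <- kader_records(c("B1", "B2", "B3", "B4"))
  fits <- lapply(recs, agdf, control = ctrl)
  m <- fosr(fits, vapply(recs, function(r) germination_index(r, 10), 0))
  # integral SSR(t) dt / integral SST(t) dt via adaptive quadrature
  Bf <- function(t) eval_basis(m$spec, t)
  ssr_t <- function(t) {
    Bt <- Bf(t)
    Yh <- m$fitted %*% t(Bt); Yo <- m$Y %*% t(Bt)
    colSums(sweep(Yh, 2L, colMeans(Yo))^2)
  }
  sst_t <- function(t) {
    Bt <- Bf(t); Yo <- m$Y %*% t(Bt)
    colSums(sweep(Yo, 2L, colMeans(Yo))^2)
  }
  num <- pracma::integral(function(t) ssr_t(t), 0, 10, reltol = 1e-12)
  den <- pracma::integral(function(t) sst_t(t), 0, 10, reltol = 1e-12)
  expect_equal(m$r2_glob, num / den, tolerance = 1e-8)
})

test_that("the index comparison reproduces the uniform-onset scenario column", {
  out <- compare_indices(c_recs, control = ctrl)
  got <- setNames(out$r2_glob, out$index)
  expect_equal(unname(got[c("TG", "GI", "CGI")]), c(1, 1, 1), tolerance = 1e-8)
  expect_true(all(is.na(got[c("LT50", "MGT", "CVG")])))
  expect_true(all(out$singular[out$index %in% c("LT50", "MGT", "CVG")]))
})

test_that("the comparison honours the zero-germination filter and input contracts", {
  recs <- kader_records(c("B1", "B2", "B3"))
  z <- germination_record(1:10, rep(0, 10), 100L, accession = "dormant")
  all4 <- c(recs, list(z = z))
  out_all <- compare_indices(all4, control = ctrl, indices = c("tg", "cgi"))
  expect_equal(unique(out_all$n), 4L)
  out_nz <- compare_indices(all4, control = ctrl, indices = c("tg", "cgi"),
                            drop_zero_germination = TRUE)
  expect_equal(unique(out_nz$n), 3L)
  # indices undefined for the dormant accession cannot be fit over the full set
  out_na <- compare_indices(all4, control = ctrl, indices = "mgt")
  expect_true(is.na(out_na$r2_glob))
  expect_error(compare_indices(recs[1:2], control = ctrl), "at least 3")
  expect_error(fosr(c_fits, c(1, 2)), "one value per curve")
  expect_error(fosr(lapply(kader_records(c("B1", "B2")), agdf), 1:2), "at least 3")
})

test_that("a speed-varying cohort at fixed total germination favours the continuous index", {
  # equal plateaus, different half-times: TG is (nearly) constant so its
  # model is singular, while the continuous index still explains the curves
  params <- lapply(c(2, 3.5, 5, 6.5, 8), function(b)
    hill_params(tg_max = 0.9, half_time = b, shape = 6, total_seeds = 500L))
  recs <- simulate_cohort(params, days = 1:10, seed = 99L)
  fits <- lapply(recs, agdf, control = ctrl)
  x_cgi <- vapply(fits, cgi, 0)
  m_cgi <- fosr(fits, x_cgi)
  expect_false(m_cgi$singular)
  expect_gt(m_cgi$r2_glob, 0.8)
  tgs <- vapply(recs, total_germination, 0)
  m_tg <- fosr(fits, tgs)
  r2_tg <- if (m_tg$singular) NA_real_ else m_tg$r2_glob
  expect_true(is.na(r2_tg) || m_cgi$r2_glob >= r2_tg)
})
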