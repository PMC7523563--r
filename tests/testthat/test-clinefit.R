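test_that("cline evaluation matches closed forms and the independent oracle", {
  m <- cline_model(185.9, 8.6)
  expect_equal(cline_value(185.9, m), 0.5)
  expect_equal(cline_value(185.9 + 8.6 / 4, m), 1 / (1 + exp(-1)))
  expect_error(cline_model(100, 0), "positive")

  set.seed(71)
  n_checked <- 0
  for (i in 1:60) {
    c0 <- runif(1, 50, 250); w <- runif(1, 2, 40)
    dl <- runif(1, 0, 60); tl <- runif(1, 0, 1)
    dr <- runif(1, 0, 60); tr <- runif(1, 0, 1)
    mm <- cline_model(c0, w, "both", delta_l = dl, tau_l = tl,
                      delta_r = dr, tau_r = tr)
    x <- sort(runif(25, -50, 350))
    expect_equal(
      cline_value(x, mm),
      oracle_cline_value(x, c0, w, dl, tl, dr, tr, left = TRUE, right = TRUE),
      tolerance = 1e-12
    )
    n_checked <- n_checked + length(x)
  }
  expect_gt(n_checked, 1000)
})

test_that("tails join the sigmoid continuously and keep the curve monotone", {
  set.seed(72)
  for (i in 1:40) {
    w <- runif(1, 2, 30); dl <- runif(1, 0.5, 50); tl <- runif(1, 0, 1)
    m <- cline_model(150, w, "both", delta_l = dl, tau_l = tl,
                     delta_r = runif(1, 0.5, 50), tau_r = runif(1, 0, 1))
    joins <- c(150 - m$delta_l, 150 + m$delta_r)
    for (j in joins) {
      expect_equal(cline_value(j - 1e-9, m), cline_value(j + 1e-9, m),
                   tolerance = 1e-6)
    }
    x <- seq(0, 300, length.out = 500)
    expect_true(all(diff(cline_value(x, m)) >= -1e-12))
  }
  # mirror ties the two tails together
  mm <- cline_model(100, 10, "mirror", delta_l = 12, tau_l = 0.4)
  expect_equal(mm$delta_r, 12)
  expect_equal(cline_value(100 - 20, mm) , 1 - cline_value(100 + 20, mm),
               tolerance = 1e-12)
})

test_that("the tailless width equals the inverse maximum slope", {
  for (w in c(5, 8.6, 20)) {
    m <- cline_model(0, w)
    x <- seq(-1, 1, length.out = 20001) * w
    slope <- max(diff(cline_value(x, m)) / diff(x))
    expect_equal(slope, 1 / w, tolerance = 1e-4)
  }
})

test_that("the binomial log-likelihood matches hand values and the dbinom oracle", {
  m <- cline_model(100, 10)
  one <- tibble::tibble(population_id = "p", distance_km = 100,
                        n_alleles = 2L, focal_allele_count = 1L)
  expect_equal(cline_loglik(m, one), 2 * log(0.5))

  set.seed(73)
  n_checked <- 0
  for (i in 1:60) {
    mm <- cline_model(runif(1, 80, 120), runif(1, 3, 30), "both",
                      delta_l = runif(1, 0, 30), tau_l = runif(1, 0, 1),
                      delta_r = runif(1, 0, 30), tau_r = runif(1, 0, 1))
    n <- sample(c(20L, 40L, 60L), 8, replace = TRUE)
    f <- tibble::tibble(
      population_id = paste0("p", 1:8),
      distance_km = sort(runif(8, 0, 200)),
      n_alleles = n,
      focal_allele_count = vapply(n, function(ni) sample(0:ni, 1), integer(1))
    )
    expect_equal(
      cline_loglik(mm, f),
      oracle_cline_loglik(f, mm$center, mm$width, mm$delta_l, mm$tau_l,
                          mm$delta_r, mm$tau_r, left = TRUE, right = TRUE),
      tolerance = 1e-9
    )
    n_checked <- n_checked + 1
  }
  expect_gt(n_checked, 50)
})

test_that("exact-frequency data maximise the likelihood at the generating cline", {
  m <- cline_model(120, 15)
  x <- seq(60, 180, by = 10)
  n <- rep(200, length(x))
  f <- tibble::tibble(
    population_id = paste0("p", seq_along(x)), distance_km = x,
    n_alleles = n, focal_allele_count = n * cline_value(x, m)
  )
  # saturated log-likelihood at the generating values
  y <- cline_value(x, m)
  sat <- sum(f$focal_allele_count * log(y) +
               (n - f$focal_allele_count) * log(1 - y))
  expect_equal(cline_loglik(m, f), sat, tolerance = 1e-9)
  for (dc in c(-20, -5, -1, 1, 5, 20)) {
    expect_lt(cline_loglik(cline_model(120 + dc, 15), f), cline_loglik(m, f))
  }
})

test_that("tailless parameter recovery from binomial sampling", {
  truth <- cline_model(185.9, 8.6)
  f <- sim_cline_counts(truth, seq(140, 230, length.out = 30), 200, seed = 20)
  fit <- fit_cline(f, "none", seed = 1)
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["center"]] - 185.9), 1)
  expect_lt(abs(fit$estimates[["width"]] - 8.6) / 8.6, 0.15)
  ci_c <- fit$ci[fit$ci$term == "center", ]
  expect_true(ci_c$conf.low <= fit$estimates[["center"]],
              ci_c$conf.high >= fit$estimates[["center"]])
  expect_lt(ci_c$conf.high - ci_c$conf.low, 10)
  expect_equal(fit$aic, 2 * fit$k - 2 * fit$logL)
})

test_that("a right-tail cline is recovered within its profile intervals", {
  truth <- cline_model(150, 10, "right", delta_r = 40, tau_r = 0.6)
  f <- sim_cline_counts(truth, seq(60, 330, length.out = 40), 60, seed = 5)
  fit <- fit_cline(f, "right", n_starts = 20, seed = 2,
                   ci_params = c("center", "width", "delta_r", "tau_r"))
  expect_true(fit$converged)
  for (p in c("delta_r", "tau_r")) {
    row <- fit$ci[fit$ci$term == p, ]
    tv <- if (p == "delta_r") 40 else 0.6
    expect_gte(tv, row$conf.low)
    expect_lte(tv, row$conf.high)
  }
})

test_that("degenerate two-population input is flagged, never silently estimated", {
  f <- tibble::tibble(
    population_id = c("a", "b"), distance_km = c(0, 100),
    n_alleles = c(40L, 40L), focal_allele_count = c(0L, 40L)
  )
  fit <- fit_cline(f, "none", n_starts = 5, seed = 1, ci = FALSE)
  expect_true(!fit$converged || any(fit$hit_bounds))
  expect_error(fit_cline(f[1, ], "none"), "at least")
  flat <- dplyr::mutate(f, focal_allele_count = c(0L, 0L))
  expect_error(fit_cline(flat, "none"), "no cline information")
})

test_that("fits are equivariant under shifting and reflecting the transect", {
  truth <- cline_model(100, 12, "both", delta_l = 10, tau_l = 0.5,
                       delta_r = 25, tau_r = 0.7)
  x <- seq(20, 180, by = 8)
  n <- rep(400L, length(x))
  f <- tibble::tibble(
    population_id = paste0("p", seq_along(x)), distance_km = x,
    n_alleles = n,
    focal_allele_count = round(n * cline_value(x, truth))
  )
  base <- fit_cline(f, "both", n_starts = 8, seed = 3, ci = FALSE)
  shifted <- f |> dplyr::mutate(distance_km = distance_km + 57)
  fs <- fit_cline(shifted, "both", n_starts = 8, seed = 3, ci = FALSE)
  expect_equal(fs$estimates[["center"]], base$estimates[["center"]] + 57,
               tolerance = 0.05)
  expect_equal(fs$estimates[["width"]], base$estimates[["width"]], tolerance = 0.02)

  reflected <- f |>
    dplyr::mutate(distance_km = 200 - distance_km,
                  focal_allele_count = n_alleles - focal_allele_count) |>
    dplyr::arrange(distance_km)
  fr <- fit_cline(reflected, "both", n_starts = 8, seed = 3, ci = FALSE)
  expect_equal(fr$estimates[["center"]], 200 - base$estimates[["center"]],
               tolerance = 0.05)
  expect_equal(fr$estimates[["width"]], base$estimates[["width"]], tolerance = 0.02)
  # the short left tail is well identified on this layout; the saturated
  # right side is a flat likelihood direction, so only the sharp side is
  # compared after the swap
  expect_equal(fr$estimates[["delta_r"]], base$estimates[["delta_l"]], tolerance = 0.1)
  expect_equal(fr$estimates[["tau_r"]], base$estimates[["tau_l"]], tolerance = 0.05)
})

test_that("AIC model selection prefers parsimony on tailless data", {
  truth <- cline_model(185.9, 8.6)
  f <- sim_cline_counts(truth, seq(140, 230, length.out = 30), 40, seed = 9)
  sel <- model_select(f, n_starts = 8, seed = 1, ci = FALSE)
  expect_equal(sel$best_tails, "none")
  expect_equal(nrow(sel$table), 5)
  expect_true(all(sel$table$AIC >= sel$best$aic - 1e-8))
})

test_that("per-locus fits summarise the parameter distribution and are deterministic", {
  set.seed(41)
  truth <- cline_model(184, 12)
  pos <- seq(120, 250, length.out = 25)
  f <- purrr::map_dfr(1:12, function(l) {
    ml <- cline_model(184 + rnorm(1, 0, 2), 12 * exp(rnorm(1, 0, 0.15)))
    sim_cline_counts(ml, pos, 40, seed = 500 + l) |>
      dplyr::mutate(locus_id = sprintf("loc_%02d", l), .before = 1)
  })
  fl <- fit_all_loci(f, tails = "both", n_starts = 4, seed = 2)
  expect_equal(nrow(fl$table), 12)
  expect_lt(abs(fl$summary$median[fl$summary$term == "center"] - 184), 3)
  fl2 <- fit_all_loci(f, tails = "both", n_starts = 4, seed = 2)
  expect_identical(fl$table, fl2$table)
  # single locus: summaries collapse to that locus's estimates
  single <- fit_all_loci(f[f$locus_id == "loc_01", ], tails = "none",
                         n_starts = 4, seed = 2)
  expect_equal(single$summary$median[single$summary$term == "center"],
               single$table$center)
})

test_that("tail asymmetry testing handles identical tails and needs enough loci", {
  tab <- tibble::tibble(
    locus_id = paste0("l", 1:8),
    delta_l = c(5, 8, 3, 9, 4, 7, 6, 2),
    delta_r = c(5, 8, 3, 9, 4, 7, 6, 2),
    tau_l = 0.5, tau_r = 0.5,
    converged = TRUE,
    delta_l_at_bound = FALSE, delta_r_at_bound = FALSE
  )
  res <- tail_asymmetry_test(tab)
  expect_equal(res$delta_p, 1)
  expect_equal(res$tau_p, 1)
  expect_error(tail_asymmetry_test(tab[1:4, ]), "usable loci")
  # strongly one-sided differences are detected
  tab2 <- dplyr::mutate(tab, delta_r = delta_l * 3 + 1)
  expect_lt(tail_asymmetry_test(tab2)$delta_p, 0.05)
})
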