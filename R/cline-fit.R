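# parameter vector layout per tail configuration
.par_names <- function(tails) {
  switch(tails,
    none = c("center", "width"),
    left = c("center", "width", "delta_l", "tau_l"),
    right = c("center", "width", "delta_r", "tau_r"),
    mirror = c("center", "width", "delta", "tau"),
    both = c("center", "width", "delta_l", "tau_l", "delta_r", "tau_r"),
    abort("unknown tail configuration")
  )
}

.par_to_model <- function(par, tails, p_min, p_max) {
  dl <- tl <- dr <- tr <- 0
  if (tails == "left") { dl <- par[3]; tl <- par[4] }
  if (tails == "right") { dr <- par[3]; tr <- par[4] }
  if (tails == "mirror") { dl <- dr <- par[3]; tl <- tr <- par[4] }
  if (tails == "both") { dl <- par[3]; tl <- par[4]; dr <- par[5]; tr <- par[6] }
  structure(
    list(center = par[1], width = par[2], tails = tails,
         delta_l = dl, tau_l = tl, delta_r = dr, tau_r = tr,
         p_min = p_min, p_max = p_max),
    class = "cline_model"
  )
}

.default_bounds <- function(x, tails) {
  span <- max(x) - min(x)
  lw <- c(min(x) - 50, 0.1)
  up <- c(max(x) + 50, 2 * span)
  k <- cline_n_par(tails)
  if (k >= 4) { lw <- c(lw, 0, 0); up <- c(up, span, 1) }
  if (k == 6) { lw <- c(lw, 0, 0); up <- c(up, span, 1) }
  nm <- .par_names(tails)
  list(lower = setNames(lw, nm), upper = setNames(up, nm))
}

# linear interpolation of the first crossing of `level` by (x, f)
.crossing <- function(x, f, level) {
  s <- f - level
  for (i in seq_len(length(x) - 1)) {
    if (!is.na(s[i]) && !is.na(s[i + 1]) && s[i] * s[i + 1] <= 0 && s[i] != s[i + 1]) {
      return(x[i] + (x[i + 1] - x[i]) * s[i] / (s[i] - s[i + 1]))
    }
  }
  NA_real_
}

.cline_inits <- function(freqs, tails, bounds) {
  x <- freqs$distance_km
  f <- freqs$focal_allele_count / freqs$n_alleles
  span <- max(x) - min(x)
  c0 <- .crossing(x, f, 0.5)
  if (is.na(c0)) c0 <- median(x)
  x2 <- .crossing(x, f, 0.2)
  x8 <- .crossing(x, f, 0.8)
  w0 <- if (!is.na(x2) && !is.na(x8) && abs(x8 - x2) > 0) abs(x8 - x2) else span / 4
  k <- cline_n_par(tails)
  init <- c(c0, w0)
  if (k >= 4) init <- c(init, span / 8, 0.5)
  if (k == 6) init <- c(init, span / 8, 0.5)
  pmin(pmax(init, bounds$lower + 1e-8), bounds$upper - 1e-8)
}

.freq_nll <- function(par, tails, x, kk, nn, p_min, p_max) {
  m <- .par_to_model(par, tails, p_min, p_max)
  y <- cline_value(x, m)
  y <- pmin(pmax(y, 1e-9), 1 - 1e-9)
  -sum(kk * log(y) + (nn - kk) * log1p(-y))
}

# specialised negative log-likelihood closure for the optimiser hot path;
# algebra identical to cline_value()/cline_loglik(), inlined to avoid
# per-evaluation model construction (verified equal in the tests)
.make_nll <- function(tails, x, kk, nn, p_min, p_max) {
  has_l <- tails %in% c("left", "mirror", "both")
  has_r <- tails %in% c("right", "mirror", "both")
  il <- c(3L, 4L)
  ir <- if (tails == "both") c(5L, 6L) else c(3L, 4L)
  scale <- p_max - p_min
  nkk <- nn - kk
  function(par) {
    ctr <- par[1]
    w <- par[2]
    y <- 1 / (1 + exp(-4 * (x - ctr) / w))
    if (has_l) {
      dl <- par[il[1]]
      lo <- x < ctr - dl
      if (any(lo)) {
        e <- exp(-4 * dl / w)
        y[lo] <- exp(4 * par[il[2]] * (x[lo] - ctr + dl) / (w * (1 + e))) /
          (1 + exp(4 * dl / w))
      }
    }
    if (has_r) {
      dr <- par[ir[1]]
      hi <- x > ctr + dr
      if (any(hi)) {
        e <- exp(-4 * dr / w)
        y[hi] <- 1 - exp(-4 * par[ir[2]] * (x[hi] - ctr - dr) / (w * (1 + e))) /
          (1 + exp(4 * dr / w))
      }
    }
    y <- p_min + scale * y
    y <- pmin(pmax(y, 1e-9), 1 - 1e-9)
    -sum(kk * log(y) + nkk * log1p(-y))
  }
}

#' Fit a geographic cline by maximum likelihood
#'
#' Maximises the binomial likelihood of [cline_model()] frequencies by
#' multi-start bounded quasi-Newton optimisation (`optim`, L-BFGS-B). The
#' first start uses moment-based initial values (the interpolated 0.5
#' crossing for the center; the distance between the 0.2 and 0.8 crossings
#' for the width); the remaining starts jitter around them. 95% confidence
#' intervals come from the profile likelihood (drop of 1.92 log-likelihood
#' units); parameters whose estimate lies on an optimisation bound are
#' flagged.
#'
#' @param freqs A population frequency table (see
#'   [validate_frequency_table()]).
#' @param tails Tail configuration (see [cline_model()]).
#' @param p_min,p_max Frequency asymptotes (defaults 0 and 1).
#' @param bounds Optional list with named `lower`/`upper` vectors; defaults
#'   to center within the sampled range +/- 50 km, width in
#'   `[0.1, 2 * span]`, tail lengths in `[0, span]`, tail slopes in `[0, 1]`.
#' @param n_starts Number of optimisation starts (default 20).
#' @param seed Seed for the start jitter.
#' @param ci Compute profile-likelihood intervals (default `TRUE`).
#' @param ci_params Parameters to profile (default center and width).
#' @return An object of class `cline_fit`: fitted model, `estimates`,
#'   `logL`, `aic`, `k`, `n_pops`, `converged`, `hit_bounds`, `ci`, and the
#'   data.
#' @export
fit_cline <- function(freqs, tails = c("none", "left", "right", "mirror", "both"),
                      p_min = 0, p_max = 1, bounds = NULL,
                      n_starts = 20L, seed = 1L,
                      ci = TRUE, ci_params = c("center", "width")) {
  tails <- match.arg(tails)
  freqs <- validate_frequency_table(freqs)
  k <- cline_n_par(tails)
  x <- freqs$distance_km
  kk <- freqs$focal_allele_count
  nn <- freqs$n_alleles
  if (nrow(freqs) < k) {
    abort(sprintf("need at least %d populations to fit a %d-parameter cline", k, k))
  }
  f <- kk / nn
  if (all(f == 0) || all(f == 1)) abort("frequencies carry no cline information")
  if (is.null(bounds)) bounds <- .default_bounds(x, tails)
  nm <- .par_names(tails)
  lower <- bounds$lower[nm]
  upper <- bounds$upper[nm]
  init0 <- .cline_inits(freqs, tails, list(lower = lower, upper = upper))
  span <- max(x) - min(x)

  set.seed(seed)
  starts <- list(init0)
  if (n_starts > 1) {
    for (i in seq_len(n_starts - 1)) {
      s <- init0
      s[1] <- s[1] + rnorm(1, 0, span / 10)
      s[2] <- s[2] * exp(rnorm(1, 0, 0.5))
      if (k >= 4) { s[3] <- runif(1, 0, span / 4); s[4] <- runif(1, 0.05, 0.95) }
      if (k == 6) { s[5] <- runif(1, 0, span / 4); s[6] <- runif(1, 0.05, 0.95) }
      starts[[i + 1]] <- pmin(pmax(s, lower + 1e-8), upper - 1e-8)
    }
  }
  nll_fun <- .make_nll(tails, x, kk, nn, p_min, p_max)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, nll_fun, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    est <- setNames(init0, nm)
    model <- .par_to_model(est, tails, p_min, p_max)
    nll <- nll_fun(est)
    converged <- FALSE
  } else {
    est <- setNames(best$par, nm)
    model <- .par_to_model(est, tails, p_min, p_max)
    nll <- best$value
    converged <- best$convergence == 0
  }
  tol <- pmax(1e-6 * (upper - lower), 1e-8)
  hit_bounds <- (est - lower < tol) | (upper - est < tol)

  # a fit with no residual degrees of freedom is exactly saturated and its
  # parameters are not jointly identified; never report it as converged
  if (nrow(freqs) <= k) converged <- FALSE
  # under-determined data leave the likelihood flat in the width; refuse to
  # report such a fit as converged (e.g. two saturated populations)
  if (converged) {
    w_probe <- pmin(pmax(c(est[2] * 0.5, est[2] * 2), lower[2]), upper[2])
    flat <- max(abs(vapply(w_probe, function(w) {
      p <- est; p[2] <- w; nll_fun(p)
    }, numeric(1)) - nll)) < 1e-6
    if (flat) converged <- FALSE
  }

  ci_tab <- NULL
  if (ci) {
    ci_tab <- purrr::map_dfr(intersect(ci_params, nm), function(p) {
      .profile_ci(p, est, nll, nll_fun, lower, upper)
    })
  }
  out <- structure(
    list(
      model = model, tails = tails, estimates = est,
      logL = -nll, aic = 2 * k + 2 * nll, k = k,
      n_pops = nrow(freqs), converged = converged,
      hit_bounds = hit_bounds, ci = ci_tab,
      data = freqs,
      bounds = list(lower = lower, upper = upper)
    ),
    class = "cline_fit"
  )
  out
}

# profile-likelihood 95% interval for one parameter
.profile_ci <- function(param, est, nll_min, nll_fun, lower, upper) {
  nm <- names(est)
  j <- match(param, nm)
  others <- setdiff(seq_along(est), j)
  prof_nll <- function(v) {
    if (length(others) == 0) {
      return(nll_fun(v))
    }
    full <- function(po) {
      par <- numeric(length(est))
      par[j] <- v
      par[others] <- po
      nll_fun(par)
    }
    fit <- tryCatch(
      optim(est[others], full, method = "L-BFGS-B",
            lower = lower[others], upper = upper[others],
            control = list(maxit = 200)),
      error = function(e) NULL
    )
    if (is.null(fit)) Inf else fit$value
  }
  target <- nll_min + qchisq(0.95, df = 1) / 2
  side <- function(bound) {
    g_bound <- prof_nll(bound) - target
    if (!is.finite(g_bound) || g_bound < 0) return(bound) # no crossing: open to the box
    root <- tryCatch(
      uniroot(function(v) prof_nll(v) - target, c(min(est[j], bound), max(est[j], bound)),
              tol = max(1e-4, 1e-4 * abs(upper[j] - lower[j])))$root,
      error = function(e) bound
    )
    root
  }
  tibble(
    term = param, estimate = unname(est[j]),
    conf.low = min(side(lower[j]), est[j]),
    conf.high = max(side(upper[j]), est[j])
  )
}

#' @export
print.cline_fit <- function(x, ...) {
  cat(sprintf(
    "<cline_fit> tails = %s (k = %d), logL = %.3f, AIC = %.2f, %d populations%s\n",
    x$tails, x$k, x$logL, x$aic, x$n_pops,
    if (x$converged) "" else " [not converged]"
  ))
  est <- x$estimates
  for (nmi in names(est)) {
    ci <- if (!is.null(x$ci) && nmi %in% x$ci$term) {
      row <- x$ci[x$ci$term == nmi, ]
      sprintf(" (95%% CI %.3g-%.3g)", row$conf.low, row$conf.high)
    } else ""
    cat(sprintf("  %-8s %.4g%s%s\n", nmi, est[nmi], ci,
                if (x$hit_bounds[nmi]) " [at bound]" else ""))
  }
  invisible(x)
}

#' @method tidy cline_fit
#' @export
tidy.cline_fit <- function(x, ...) {
  out <- tibble(
    term = names(x$estimates),
    estimate = unname(x$estimates),
    at_bound = unname(x$hit_bounds)
  )
  if (!is.null(x$ci)) {
    out <- out %>% left_join(x$ci %>% select(-"estimate"), by = "term")
  }
  out
}

#' @method glance cline_fit
#' @export
glance.cline_fit <- function(x, ...) {
  tibble(
    tails = x$tails, k = x$k, logL = x$logL, AIC = x$aic,
    n_pops = x$n_pops, converged = x$converged,
    any_bound = any(x$hit_bounds)
  )
}

#' AIC model selection over tail configurations
#'
#' Fits every requested tail configuration and picks the fit with minimal
#' AIC (`2k - 2 logL`), breaking ties toward fewer parameters. Only
#' converged fits compete; per-configuration failures are recorded.
#'
#' @param freqs A population frequency table.
#' @param configs Tail configurations to compare (default all five).
#' @param ... Passed to [fit_cline()].
#' @return A list of class `cline_model_select`: `best` (a `cline_fit`),
#'   `best_tails`, `fits` (named list), `table` (one [glance()] row per
#'   configuration).
#' @export
model_select <- function(freqs,
                         configs = c("none", "left", "right", "mirror", "both"),
                         ...) {
  fits <- purrr::map(configs, function(cfg) {
    tryCatch(fit_cline(freqs, tails = cfg, ...), error = function(e) e)
  })
  names(fits) <- configs
  ok <- !purrr::map_lgl(fits, inherits, "error")
  table <- purrr::map_dfr(fits[ok], glance)
  conv <- table$converged
  if (!any(conv)) abort("no tail configuration converged")
  tc <- table[conv, ]
  ord <- order(tc$AIC, tc$k)
  best_tails <- tc$tails[ord[1]]
  structure(
    list(
      best = fits[[best_tails]], best_tails = best_tails,
      fits = fits[ok], table = table,
      failed = names(fits)[!ok]
    ),
    class = "cline_model_select"
  )
}

#' @export
print.cline_model_select <- function(x, ...) {
  cat(sprintf("<cline_model_select> best: %s (AIC %.2f of %d configurations)\n",
              x$best_tails, x$best$aic, nrow(x$table)))
  invisible(x)
}

#' @method tidy cline_model_select
#' @export
tidy.cline_model_select <- function(x, ...) x$table

#' Independent cline fits for many loci
#'
#' Fits one cline per locus (six-parameter, both-tail models by default, for
#' comparability across loci) and summarises the distribution of every
#' parameter across loci by its median and central 95% range. Loci whose
#' fits fail or do not converge are excluded from the summaries and counted.
#'
#' @param freqs A frequency table with a `locus_id` column stacking one
#'   table per locus.
#' @param tails Tail configuration used for every locus (default `"both"`).
#' @param n_starts,seed,ci,... Passed to [fit_cline()]; each locus uses an
#'   independently derived seed. CIs default to off for speed.
#' @return A list of class `locus_cline_fits`: `fits` (named list),
#'   `table` (one row per locus with estimates and bound flags), `summary`
#'   (median/2.5%/97.5% per parameter), `n_failed`.
#' @export
fit_all_loci <- function(freqs, tails = "both", n_starts = 10L, seed = 1L,
                         ci = FALSE, ...) {
  if (!"locus_id" %in% names(freqs)) abort("freqs needs a locus_id column")
  ids <- unique(freqs$locus_id)
  if (length(ids) == 0) abort("no loci in the table")
  fits <- purrr::map(seq_along(ids), function(i) {
    sub <- freqs[freqs$locus_id == ids[i], setdiff(names(freqs), "locus_id")]
    tryCatch(
      fit_cline(sub, tails = tails, n_starts = n_starts,
                seed = seed + i - 1L, ci = ci, ...),
      error = function(e) e
    )
  })
  names(fits) <- ids
  ok <- !purrr::map_lgl(fits, inherits, "error")
  table <- purrr::map_dfr(which(ok), function(i) {
    f <- fits[[i]]
    est <- as_tibble(as.list(f$estimates))
    bnd <- as_tibble(as.list(setNames(f$hit_bounds,
                                      paste0(names(f$hit_bounds), "_at_bound"))))
    dplyr::bind_cols(tibble(locus_id = ids[i]), est, bnd,
                     tibble(logL = f$logL, aic = f$aic, converged = f$converged))
  })
  usable <- table[table$converged, ]
  par_cols <- intersect(.par_names(tails), names(table))
  summary <- purrr::map_dfr(par_cols, function(p) {
    v <- usable[[p]]
    tibble(
      term = p, median = median(v),
      q2.5 = unname(quantile(v, 0.025)), q97.5 = unname(quantile(v, 0.975))
    )
  })
  structure(
    list(
      fits = fits, table = table, summary = summary,
      n_failed = sum(!ok) + sum(ok) - nrow(usable),
      tails = tails
    ),
    class = "locus_cline_fits"
  )
}

#' @export
print.locus_cline_fits <- function(x, ...) {
  cat(sprintf("<locus_cline_fits> %d loci (%d unusable), tails = %s\n",
              nrow(x$table), x$n_failed, x$tails))
  print(x$summary)
  invisible(x)
}

#' @method tidy locus_cline_fits
#' @export
tidy.locus_cline_fits <- function(x, ...) x$table

#' @method glance locus_cline_fits
#' @export
glance.locus_cline_fits <- function(x, ...) {
  x$summary %>%
    tidyr::pivot_wider(names_from = "term",
                       values_from = c("median", "q2.5", "q97.5"))
}

#' Paired test of introgression-tail asymmetry
#'
#' Compares the left and right tail lengths (`delta_l` vs `delta_r`) and
#' slopes (`tau_l` vs `tau_r`) across per-locus both-tail fits with
#' two-sided paired Wilcoxon signed-rank tests. Asymmetric introgression —
#' alleles escaping further on one side of the zone — shows up as longer
#' and steeper tails on that side. Loci that did not converge or whose two
#' tail lengths both sit on an optimisation bound are dropped and counted.
#'
#' @param fits A [fit_all_loci()] result (or its `table`).
#' @param min_loci Minimum usable loci (default 6).
#' @return A list of class `tail_asymmetry`: `delta_p`, `tau_p`, per-side
#'   medians, `n_used`, `n_dropped`.
#' @export
tail_asymmetry_test <- function(fits, min_loci = 6L) {
  tab <- if (inherits(fits, "locus_cline_fits")) fits$table else as_tibble(fits)
  need <- c("delta_l", "delta_r", "tau_l", "tau_r", "converged")
  if (!all(need %in% names(tab))) {
    abort("need per-locus both-tail fits (delta/tau on both sides)")
  }
  both_bound <- if (all(c("delta_l_at_bound", "delta_r_at_bound") %in% names(tab))) {
    tab$delta_l_at_bound & tab$delta_r_at_bound
  } else {
    rep(FALSE, nrow(tab))
  }
  usable <- tab$converged & !both_bound
  n_used <- sum(usable)
  if (n_used < min_loci) {
    abort(sprintf("only %d usable loci (need >= %d)", n_used, min_loci))
  }
  tab <- tab[usable, ]
  wtest <- function(a, b) {
    if (all(a == b)) return(1)
    suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
  }
  structure(
    list(
      delta_p = wtest(tab$delta_l, tab$delta_r),
      tau_p = wtest(tab$tau_l, tab$tau_r),
      median_delta_l = median(tab$delta_l), median_delta_r = median(tab$delta_r),
      median_tau_l = median(tab$tau_l), median_tau_r = median(tab$tau_r),
      n_used = n_used, n_dropped = sum(!usable)
    ),
    class = "tail_asymmetry"
  )
}

#' @export
print.tail_asymmetry <- function(x, ...) {
  cat(sprintf(
    paste0("<tail_asymmetry> %d loci (%d dropped)\n",
           "  delta: medians %.3g (L) vs %.3g (R), p = %.4g\n",
           "  tau:   medians %.3g (L) vs %.3g (R), p = %.4g\n"),
    x$n_used, x$n_dropped,
    x$median_delta_l, x$median_delta_r, x$delta_p,
    x$median_tau_l, x$median_tau_r, x$tau_p
  ))
  invisible(x)
}

#' @method glance tail_asymmetry
#' @export
glance.tail_asymmetry <- function(x, ...) {
  tibble(
    delta_p = x$delta_p, tau_p = x$tau_p,
    median_delta_l = x$median_delta_l, median_delta_r = x$median_delta_r,
    median_tau_l = x$median_tau_l, median_tau_r = x$median_tau_r,
    n_used = x$n_used, n_dropped = x$n_dropped
  )
}
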