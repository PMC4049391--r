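#' @title Growth-constant (kG) estimation from complemented-yeast growth
#' @description
#' Estimates a heterologously expressed transporter's apparent substrate
#' affinity from the growth of a complemented yeast mutant on a range of
#' external substrate concentrations. Each optical-density time series is
#' fitted with exponential growth, A600(t) = A600(t0) * exp(k t); rates are
#' expressed as inverse duplication times, dt^-1 = k / ln 2; and the
#' rate-versus-substrate isotherm is fitted with a Michaelis-Menten
#' hyperbola, rate(S) = k_max * S / (k_G + S). The growth constant k_G — the
#' substrate concentration at half-maximal growth rate — approximates the
#' transporter's Michaelis constant k_M whenever growth is limited by
#' substrate uptake; [check_transport_limitation()] encodes the validity
#' checks for that assumption.
#' @name growth_kinetics
NULL

# Running simple linear regression of y on x over every contiguous window
# via cumulative sums; returns slope/intercept/r2 for one window.
window_ols <- function(cx, cy, cxx, cyy, cxy, i, j) {
  n <- j - i + 1
  sx <- cx[j + 1] - cx[i]; sy <- cy[j + 1] - cy[i]
  sxx <- cxx[j + 1] - cxx[i]; syy <- cyy[j + 1] - cyy[i]
  sxy <- cxy[j + 1] - cxy[i]
  vx <- sxx - sx^2 / n
  vy <- syy - sy^2 / n
  cxy_ <- sxy - sx * sy / n
  slope <- cxy_ / vx
  r2 <- if (vy <= 1e-14 * max(syy, 1)) 1 else cxy_^2 / (vx * vy)
  list(n = n, slope = slope, intercept = (sy - slope * sx) / n, r2 = r2)
}

#' Fit exponential growth to an optical-density time series
#'
#' Fits `A600(t) = A0 * exp(k t)` by linear regression of `log(od)` on time.
#' If no window is given, the exponential phase is auto-selected as the
#' longest contiguous run of at least `min_points` time points whose
#' log-linear r-squared is at least `r2_min` (ties broken by the higher
#' r-squared); this excludes lag and stationary phases, for which the
#' published protocol gives no explicit rule.
#'
#' @param times Time points (hours), strictly increasing, >= 4.
#' @param od Optical densities (A600), same length, > 0 within the fitted
#'   window.
#' @param window Optional integer vector of indices to fit (length >= 4);
#'   overrides auto-selection.
#' @param min_points Minimum window length for auto-selection.
#' @param r2_min Minimum log-linear r-squared for a window to qualify.
#' @param blank Constant blank OD subtracted before fitting (default 0).
#' @return An `exp_fit`: `k` (h^-1), `A0`, `window` (indices used), `r2`,
#'   `se_k`, `n`.
#' @examples
#' t <- 0:10
#' fit_exponential(t, 0.1 * exp(0.2 * t))$k  # 0.2
#' @export
fit_exponential <- function(times, od, window = NULL, min_points = 4,
                            r2_min = 0.98, blank = 0) {
  if (length(times) != length(od)) stop_usage("times and od differ in length")
  if (length(times) < 4) stop_usage("need >= 4 time points")
  if (any(diff(times) <= 0)) stop_usage("times must be strictly increasing")
  od <- od - blank
  if (!is.null(window)) {
    window <- sort(unique(as.integer(window)))
    if (length(window) < 4 || any(window < 1) || any(window > length(od))) {
      stop_usage("window must select >= 4 valid points")
    }
    if (any(od[window] <= 0)) stop_usage("od must be > 0 within the window")
    idx <- window
  } else {
    pos <- od > 0
    x <- times; y <- ifelse(pos, log(pmax(od, 1e-300)), NA_real_)
    n <- length(x)
    cx <- c(0, cumsum(x)); cy <- c(0, cumsum(ifelse(pos, y, 0)))
    cxx <- c(0, cumsum(x^2)); cyy <- c(0, cumsum(ifelse(pos, y^2, 0)))
    cxy <- c(0, cumsum(ifelse(pos, x * y, 0)))
    cpos <- c(0, cumsum(pos))
    best <- NULL
    for (i in seq_len(n - min_points + 1)) {
      for (j in seq(i + min_points - 1, n)) {
        if (cpos[j + 1] - cpos[i] < j - i + 1) next  # window has od <= 0
        w <- window_ols(cx, cy, cxx, cyy, cxy, i, j)
        if (w$r2 >= r2_min) {
          if (is.null(best) || w$n > best$n ||
              (w$n == best$n && w$r2 > best$r2)) {
            best <- c(w, list(i = i, j = j))
          }
        }
      }
    }
    if (is.null(best)) {
      stop_compute("no exponential phase detected (no window of >= %d points with r2 >= %g)",
                   min_points, r2_min)
    }
    # trim boundary points (lag / early-stationary stragglers) while doing
    # so still improves the fit appreciably
    i <- best$i; j <- best$j; r2 <- best$r2
    gain_min <- 0.2   # fraction of the remaining misfit a trim must explain
    while (j - i + 1 > min_points) {
      left <- window_ols(cx, cy, cxx, cyy, cxy, i + 1, j)
      right <- window_ols(cx, cy, cxx, cyy, cxy, i, j - 1)
      cand <- if (left$r2 >= right$r2) list(r2 = left$r2, side = "l")
              else list(r2 = right$r2, side = "r")
      if (cand$r2 - r2 <= gain_min * (1 - r2) + 1e-9) break
      if (cand$side == "l") i <- i + 1 else j <- j - 1
      r2 <- cand$r2
    }
    idx <- i:j
  }
  x <- times[idx]; y <- log(od[idx])
  if (sd(y) < 1e-12) {
    # flat culture: k = 0 exactly, no log-linear variance to explain
    return(structure(list(k = 0, A0 = exp(mean(y)), window = idx, r2 = 1,
                          se_k = 0, n = length(idx)), class = "exp_fit"))
  }
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))  # noise-free fits are "too perfect"
  structure(
    list(k = unname(coef(fit)[2]), A0 = unname(exp(coef(fit)[1])),
         window = idx, r2 = sm$r.squared,
         se_k = unname(sm$coefficients[2, 2]), n = length(idx)),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  cat(sprintf("<exp_fit> k = %.4g h^-1 (se %.3g), A0 = %.4g, %d points, r2 = %.4f\n",
              x$k, x$se_k, x$A0, x$n, x$r2))
  invisible(x)
}

#' Growth rate (inverse duplication time) from an exponential fit
#'
#' The duplication time is `dt = ln 2 / k`; the growth rate reported on the
#' isotherm is `dt^-1 = k / ln 2` (duplications per hour). A declining
#' culture (k < 0) is clamped to rate 0 with a warning.
#'
#' @param fit An `exp_fit`, or a numeric rate constant `k` (h^-1).
#' @return Growth rate in dt^-1 (h^-1); `attr(, "se")` carries the
#'   propagated standard error when `fit` is an `exp_fit`.
#' @examples
#' growth_rate(log(2))  # doubling every hour -> rate 1
#' @export
growth_rate <- function(fit) {
  k <- if (inherits(fit, "exp_fit")) fit$k else fit
  se <- if (inherits(fit, "exp_fit")) fit$se_k else NA_real_
  if (any(k < 0)) {
    warning("negative growth constant: declining culture, rate clamped to 0")
  }
  rate <- pmax(k, 0) / log(2)
  attr(rate, "se") <- se / log(2)
  rate
}

#' Fit a Michaelis-Menten hyperbola to a rate-versus-substrate isotherm
#'
#' Nonlinear least squares of `rate(S) = k_max * S / (k_G + S)`, initialised
#' from a Hanes-Woolf linearisation (`S/v` regressed on `S`), with
#' positivity enforced. When per-concentration standard errors are supplied
#' the fit is weighted by inverse variance.
#'
#' @param isotherm Data frame with columns `conc` (substrate, uM) and `rate`
#'   (dt^-1, h^-1), optionally `se`; one row per concentration.
#' @param weighted Use 1/se^2 weights when `se` is available (default TRUE).
#' @return An `mm_fit`: `k_max`, `k_G`, `se_kmax`, `se_kG`, `rss`, `df`,
#'   plus the data and fitted values.
#' @examples
#' S <- c(1, 2.5, 5, 10, 25, 100)
#' fit_mm(data.frame(conc = S, rate = 0.1 * S / (5 + S)))
#' @export
fit_mm <- function(isotherm, weighted = TRUE) {
  if (!all(c("conc", "rate") %in% names(isotherm))) {
    stop_usage("isotherm needs columns 'conc' and 'rate'")
  }
  d <- isotherm[is.finite(isotherm$conc) & is.finite(isotherm$rate), ]
  if (anyDuplicated(d$conc)) {
    stop_usage("one isotherm entry per concentration; average replicates first")
  }
  if (all(d$rate == 0)) stop_compute("all growth rates are zero; cannot fit")
  if (length(unique(d$conc)) < 4) {
    warning("fewer than 4 distinct concentrations: Michaelis-Menten fit is fragile")
  }
  pos <- d$conc > 0 & d$rate > 0
  if (sum(pos) >= 2) {
    hw <- lm(I(conc / rate) ~ conc, data = d[pos, ])
    k_max0 <- 1 / coef(hw)[2]
    k_G0 <- coef(hw)[1] * k_max0
  } else {
    k_max0 <- max(d$rate); k_G0 <- stats::median(d$conc[d$conc > 0])
  }
  if (!is.finite(k_max0) || k_max0 <= 0) k_max0 <- max(d$rate)
  if (!is.finite(k_G0) || k_G0 <= 0) k_G0 <- stats::median(d$conc[d$conc > 0])
  w <- if (weighted && "se" %in% names(d) && all(is.finite(d$se)) &&
           all(d$se > 0)) 1 / d$se^2 else rep(1, nrow(d))
  fit <- tryCatch(
    nls(rate ~ k_max * conc / (k_G + conc), data = d,
        start = list(k_max = k_max0, k_G = k_G0), weights = w,
        algorithm = "port", lower = c(k_max = 1e-12, k_G = 1e-12),
        control = stats::nls.control(maxiter = 200, tol = 1e-10,
                                     warnOnly = FALSE)),
    error = function(e) {
      stop_compute("Michaelis-Menten fit did not converge: %s (starts k_max=%.3g, k_G=%.3g)",
                   conditionMessage(e), k_max0, k_G0)
    }
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA, NA))
  structure(
    list(k_max = unname(est["k_max"]), k_G = unname(est["k_G"]),
         se_kmax = unname(se[1]), se_kG = unname(se[2]),
         rss = sum(stats::residuals(fit)^2), df = nrow(d) - 2,
         isotherm = d, fitted = stats::fitted(fit), nls = fit),
    class = "mm_fit"
  )
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("<mm_fit> k_max = %.4g +/- %.2g dt^-1 h^-1, k_G = %.4g +/- %.2g uM (n = %d)\n",
              x$k_max, x$se_kmax, x$k_G, x$se_kG, nrow(x$isotherm)))
  invisible(x)
}

#' Predicted Michaelis-Menten rate at given substrate concentrations
#' @param fit An `mm_fit`.
#' @param conc Substrate concentrations (uM).
#' @return Predicted growth rates (dt^-1 h^-1).
#' @export
predict_mm <- function(fit, conc) {
  fit$k_max * conc / (fit$k_G + conc)
}

#' Classify a transporter as high- or low-affinity from its growth constant
#'
#' High-affinity transporters have half-saturation constants in the
#' micromolar range; the default boundary of 100 uM separates the group-1
#' high-affinity sulfate transporters from low-affinity carriers whose k_M
#' lies in the hundreds of micromolar.
#'
#' @param fit An `mm_fit` (or a numeric k_G in uM).
#' @param threshold_uM Inclusive boundary: `k_G <= threshold` is "high".
#' @return `"high"` or `"low"`.
#' @examples
#' classify_affinity(5.46)  # "high"
#' @export
classify_affinity <- function(fit, threshold_uM = 100) {
  k_G <- if (inherits(fit, "mm_fit")) fit$k_G else fit
  if (!is.finite(k_G) || k_G <= 0) stop_usage("invalid k_G")
  if (k_G <= threshold_uM) "high" else "low"
}

#' Validity checks for equating the growth constant with the Michaelis constant
#'
#' k_G approximates the transporter's k_M only when growth is limited by
#' substrate uptake. Three observable conditions support that: (1) the
#' internal substrate store (per A600 unit) does not rise with external
#' concentration — assimilation keeps pace with uptake (tested as absence of
#' a significant Spearman monotone trend); (2) cells grow faster on an
#' organic source of the nutrient than at the highest substrate
#' concentration — downstream metabolism is not the bottleneck; (3) the
#' internal store under substrate-free starvation is near zero (default
#' threshold 0.05 nmol per A600 unit).
#'
#' @param internal_store Data frame `external_uM`, `store_nmol_per_A600`
#'   (>= 3 external concentrations).
#' @param organic_rate Growth rate (dt^-1) on the organic source, or `NA` if
#'   the control is missing.
#' @param max_substrate_rate Growth rate (dt^-1) at the highest substrate
#'   concentration tested.
#' @param zero_S_store Internal store measured at zero external substrate.
#' @param store_threshold Threshold for check (3), nmol per A600 unit.
#' @param alpha Significance level for the trend test.
#' @return A `limitation_report`: the three booleans, `overall_valid` (their
#'   conjunction), and supporting values.
#' @export
check_transport_limitation <- function(internal_store, organic_rate,
                                       max_substrate_rate, zero_S_store,
                                       store_threshold = 0.05, alpha = 0.05) {
  need <- c("external_uM", "store_nmol_per_A600")
  if (!all(need %in% names(internal_store))) {
    stop_usage("internal_store needs columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(internal_store) < 3) {
    stop_usage("internal_store needs >= 3 external concentrations")
  }
  trend <- suppressWarnings(
    cor.test(internal_store$external_uM, internal_store$store_nmol_per_A600,
             method = "spearman", exact = FALSE)
  )
  flat <- trend$p.value >= alpha
  reasons <- character(0)
  if (is.na(organic_rate)) {
    faster <- NA
    reasons <- c(reasons, "organic-source growth control missing")
  } else {
    faster <- organic_rate > max_substrate_rate
    if (!faster) reasons <- c(reasons, "organic source is not faster than saturating substrate")
  }
  low0 <- zero_S_store < store_threshold
  if (!flat) reasons <- c(reasons, "internal store rises with external concentration")
  if (!low0) reasons <- c(reasons, "starvation internal store above threshold")
  structure(
    list(internal_store_flat = flat,
         organic_source_faster = faster,
         zero_substrate_store_low = low0,
         overall_valid = isTRUE(flat) && isTRUE(faster) && isTRUE(low0),
         reasons = reasons,
         supporting = list(trend_p = trend$p.value, rho = unname(trend$estimate),
                           organic_rate = organic_rate,
                           max_substrate_rate = max_substrate_rate,
                           zero_S_store = zero_S_store,
                           store_threshold = store_threshold)),
    class = "limitation_report"
  )
}

#' @export
print.limitation_report <- function(x, ...) {
  ok <- function(b) if (is.na(b)) "indeterminate" else if (b) "yes" else "NO"
  cat("<limitation_report>\n",
      sprintf("  internal store flat across external S : %s (Spearman p = %.3g)\n",
              ok(x$internal_store_flat), x$supporting$trend_p),
      sprintf("  organic source grows faster           : %s\n",
              ok(x$organic_source_faster)),
      sprintf("  starvation store below %.3g           : %s\n",
              x$supporting$store_threshold, ok(x$zero_substrate_store_low)),
      sprintf("  k_G ~ k_M assumption valid            : %s\n",
              ok(x$overall_valid)), sep = "")
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = "; "), "\n")
  invisible(x)
}

#' Full growth-constant estimation pipeline
#'
#' From a tidy growth table (one OD reading per substrate concentration,
#' time and replicate) to the fitted growth constant: each
#' concentration-replicate curve is fitted with [fit_exponential()], rates
#' are averaged across replicates per concentration (mean and SE), and the
#' isotherm is fitted with [fit_mm()]. The zero-substrate curve is excluded
#' by default: residual growth at S = 0 reflects internal stores, not
#' transport.
#'
#' @param growth Data frame with columns `substrate_uM`, `time_h`, `od`,
#'   `replicate`.
#' @param include_zero Keep the S = 0 rates in the fit (default FALSE).
#' @param window,min_points,r2_min,blank Passed to [fit_exponential()].
#' @param weighted Passed to [fit_mm()].
#' @return List: `fits` (per concentration x replicate `exp_fit`s),
#'   `isotherm` (conc, rate, se, n), `mm` (the `mm_fit`), `affinity`.
#' @export
estimate_growth_constant <- function(growth, include_zero = FALSE,
                                     window = NULL, min_points = 4,
                                     r2_min = 0.98, blank = 0,
                                     weighted = TRUE) {
  need <- c("substrate_uM", "time_h", "od", "replicate")
  if (!all(need %in% names(growth))) {
    stop_usage("growth table needs columns: %s", paste(need, collapse = ", "))
  }
  cells <- split(growth, list(growth$substrate_uM, growth$replicate),
                 drop = TRUE)
  per_curve <- do.call(rbind, lapply(cells, function(g) {
    g <- g[order(g$time_h), ]
    fit <- tryCatch(
      fit_exponential(g$time_h, g$od, window = window,
                      min_points = min_points, r2_min = r2_min,
                      blank = blank),
      capsquant_computation_error = function(e) {
        # a substrate-free culture shows no exponential phase: rate 0
        if (g$substrate_uM[1] == 0) {
          structure(list(k = 0, A0 = mean(g$od), window = integer(0),
                         r2 = NA_real_, se_k = NA_real_, n = 0),
                    class = "exp_fit")
        } else {
          stop(e)
        }
      }
    )
    rate <- if (g$substrate_uM[1] == 0) {
      # noise on a flat culture can fake a short declining "phase"
      suppressWarnings(as.numeric(growth_rate(fit)))
    } else {
      as.numeric(growth_rate(fit))
    }
    data.frame(substrate_uM = g$substrate_uM[1], replicate = g$replicate[1],
               k = fit$k, rate = rate, r2 = fit$r2)
  }))
  rownames(per_curve) <- NULL
  iso <- do.call(rbind, lapply(split(per_curve, per_curve$substrate_uM),
                               function(g) data.frame(
    conc = g$substrate_uM[1], rate = mean(g$rate),
    se = if (nrow(g) > 1) sd(g$rate) / sqrt(nrow(g)) else NA_real_,
    n = nrow(g)
  )))
  iso <- iso[order(iso$conc), ]
  rownames(iso) <- NULL
  fit_iso <- if (include_zero) iso else iso[iso$conc > 0, ]
  mm <- fit_mm(fit_iso, weighted = weighted)
  list(fits = per_curve, isotherm = iso, mm = mm,
       affinity = classify_affinity(mm))
}
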