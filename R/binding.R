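#' The EMSA titration lane series
#'
#' Protein concentrations (nM) of the ten-lane titration used for the
#' degenerate-code gels: 0, 0.8, 1.6, 3.2, 6.25, 12.5, 25, 50, 100, 200.
#'
#' @return numeric vector of concentrations in nM
#' @export
emsa_lane_series <- function() {
  c(0, 0.8, 1.6, 3.2, 6.25, 12.5, 25, 50, 100, 200)
}

#' Construct a binding curve
#'
#' @param conc_nM protein concentrations in nM; non-negative, strictly
#'   increasing, at least 4 points
#' @param fraction_bound fraction of probe shifted, in \[0, 1\]
#' @param probe_nM probe concentration in nM (default 2, the radiolabelled
#'   probe level of the assay)
#' @return an object of class `binding_curve`
#' @export
binding_curve <- function(conc_nM, fraction_bound, probe_nM = 2) {
  conc_nM <- as.numeric(conc_nM)
  fraction_bound <- as.numeric(fraction_bound)
  if (length(conc_nM) != length(fraction_bound)) {
    stop("conc_nM and fraction_bound must have equal length", call. = FALSE)
  }
  if (length(conc_nM) < 4L) stop("need at least 4 titration points", call. = FALSE)
  if (any(conc_nM < 0)) stop("concentrations must be non-negative", call. = FALSE)
  if (any(diff(conc_nM) <= 0)) {
    stop("concentrations must be strictly increasing", call. = FALSE)
  }
  if (any(fraction_bound < 0 | fraction_bound > 1)) {
    stop("fraction_bound must lie in [0, 1]", call. = FALSE)
  }
  structure(list(conc_nM = conc_nM, fraction_bound = fraction_bound,
                 probe_nM = probe_nM), class = "binding_curve")
}

#' @rdname binding_curve
#' @param path TSV file with columns `conc_nM` and `fraction_bound`
#' @export
read_binding_curve <- function(path, probe_nM = 2) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("conc_nM", "fraction_bound") %in% names(df))) {
    stop("titration TSV needs columns 'conc_nM' and 'fraction_bound'",
         call. = FALSE)
  }
  binding_curve(df$conc_nM, df$fraction_bound, probe_nM = probe_nM)
}

#' @export
print.binding_curve <- function(x, ...) {
  cat("<binding curve>", length(x$conc_nM), "points,",
      min(x$conc_nM), "-", max(x$conc_nM), "nM; probe", x$probe_nM, "nM\n")
  invisible(x)
}

# Protein-excess isotherm. Valid because the probe (2 nM) sits well below
# the dissociation constants of interest (>= 15 nM), so free protein is
# approximately total protein.
.isotherm <- function(P, kd, hill = 1) {
  ifelse(P <= 0, 0, P^hill / (kd^hill + P^hill))
}

# Exact 1:1 solution without the protein-excess approximation: fraction of
# probe R bound at total protein P, the root of a quadratic in [PR].
.isotherm_exact <- function(P, kd, probe) {
  s <- P + probe + kd
  (s - sqrt(pmax(s^2 - 4 * P * probe, 0))) / (2 * probe)
}

.sse_kd <- function(kd, curve, hill, exact_probe) {
  f <- if (exact_probe) .isotherm_exact(curve$conc_nM, kd, curve$probe_nM)
       else .isotherm(curve$conc_nM, kd, hill)
  sum((curve$fraction_bound - f)^2)
}

# 1-D Gauss-Newton refinement of kd (hill fixed), damped so the step never
# leaves kd > 0 or increases the SSE. Converges to machine precision on
# clean data where nls() would stall on zero residuals.
.refine_kd <- function(kd, curve, hill, exact_probe, iters = 60L) {
  sse <- .sse_kd(kd, curve, hill, exact_probe)
  for (it in seq_len(iters)) {
    eps <- max(1e-8, 1e-8 * kd)
    g <- (.sse_kd(kd + eps, curve, hill, exact_probe) -
          .sse_kd(kd - eps, curve, hill, exact_probe)) / (2 * eps)
    h <- (.sse_kd(kd + eps, curve, hill, exact_probe) - 2 * sse +
          .sse_kd(kd - eps, curve, hill, exact_probe)) / eps^2
    step <- if (is.finite(h) && h > 0) -g / h else -sign(g) * 0.1 * kd
    for (bt in 1:30) {
      cand <- kd + step
      if (cand > 0) {
        s2 <- .sse_kd(cand, curve, hill, exact_probe)
        if (s2 <= sse) { kd <- cand; sse <- s2; break }
      }
      step <- step / 2
    }
    if (abs(step) < 1e-12 * max(kd, 1)) break
  }
  list(kd = kd, sse = sse)
}

#' Fit a dissociation constant to a titration
#'
#' Fits the protein-excess isotherm f = \[P\]^h / (Kd^h + \[P\]^h) by
#' nonlinear least squares. Kd is initialized at the concentration nearest
#' half-maximal binding, scanned on a log grid and refined by damped
#' Gauss-Newton. The Hill coefficient is fixed at 1 by default (the
#' complexes bind as simple 1:1 monomers); `fix_hill = FALSE` frees it.
#' `exact_probe = TRUE` replaces the protein-excess approximation with the
#' exact quadratic 1:1 solution at the curve's probe concentration.
#'
#' @param curve a `binding_curve`
#' @param fix_hill keep the Hill coefficient at 1 (default TRUE)
#' @param exact_probe use the exact quadratic binding solution
#' @param bootstrap number of case-resampling bootstrap replicates for a
#'   95% interval (0 skips it)
#' @param seed RNG seed for the bootstrap
#' @return a `kd_fit`: `kd` (nM), `hill`, `rss`, and `ci` (2-vector, nM)
#'   when bootstrapped
#' @export
fit_kd <- function(curve, fix_hill = TRUE, exact_probe = FALSE,
                   bootstrap = 0L, seed = NULL) {
  stopifnot(inherits(curve, "binding_curve"))
  if (all(curve$fraction_bound <= 0)) {
    stop("no binding detected: all fraction_bound values are zero", call. = FALSE)
  }
  fit_one <- function(cv) {
    fmax <- max(cv$fraction_bound)
    kd0 <- cv$conc_nM[which.min(abs(cv$fraction_bound - fmax / 2))]
    if (kd0 <= 0) kd0 <- max(min(cv$conc_nM[cv$conc_nM > 0]), 1e-3)
    if (fix_hill) {
      grid <- kd0 * 10^seq(-2, 2, length.out = 41)
      sses <- vapply(grid, .sse_kd, numeric(1), curve = cv, hill = 1,
                     exact_probe = exact_probe)
      ref <- .refine_kd(grid[which.min(sses)], cv, 1, exact_probe)
      list(kd = ref$kd, hill = 1, rss = ref$sse)
    } else {
      obj <- function(par) {
        f <- .isotherm(cv$conc_nM, exp(par[1]), exp(par[2]))
        sum((cv$fraction_bound - f)^2)
      }
      op <- stats::optim(c(log(kd0), 0), obj, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-14))
      if (op$convergence != 0) {
        stop("Kd fit did not converge (optim code ", op$convergence, ")",
             call. = FALSE)
      }
      list(kd = exp(op$par[1]), hill = exp(op$par[2]), rss = op$value)
    }
  }
  fit <- fit_one(curve)
  ci <- NULL
  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    n <- length(curve$conc_nM)
    kds <- vapply(seq_len(bootstrap), function(r) {
      idx <- sort(sample.int(n, n, replace = TRUE))
      cv <- list(conc_nM = curve$conc_nM[idx],
                 fraction_bound = curve$fraction_bound[idx],
                 probe_nM = curve$probe_nM)
      tryCatch(fit_one(cv)$kd, error = function(e) NA_real_)
    }, numeric(1))
    kds <- kds[is.finite(kds)]
    ci <- unname(stats::quantile(kds, c(0.025, 0.975)))
    ci <- c(min(ci[1], fit$kd), max(ci[2], fit$kd))
  }
  structure(list(kd = fit$kd, hill = fit$hill, rss = fit$rss, ci = ci,
                 n_boot = if (bootstrap > 0L) bootstrap else 0L),
            class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  cat(sprintf("<Kd fit> Kd = %.3g nM (hill %.3g, RSS %.3g)\n",
              x$kd, x$hill, x$rss))
  if (!is.null(x$ci)) {
    cat(sprintf("  bootstrap 95%% CI: %.3g - %.3g nM (%d resamples)\n",
                x$ci[1], x$ci[2], x$n_boot))
  }
  invisible(x)
}

#' Simulate an EMSA-style titration
#'
#' Draws fraction-bound values from the protein-excess isotherm with
#' truncated Gaussian noise (clipped to \[0, 1\]). Deterministic under a
#' fixed seed.
#'
#' @param kd true dissociation constant in nM (> 0)
#' @param concentrations protein concentrations in nM; default the
#'   ten-lane series of [emsa_lane_series()]
#' @param noise_sd Gaussian noise standard deviation (default 0)
#' @param seed RNG seed
#' @param hill Hill coefficient of the generating model (default 1)
#' @param probe_nM probe concentration recorded on the curve (default 2)
#' @return a `binding_curve`
#' @export
simulate_titration <- function(kd, concentrations = emsa_lane_series(),
                               noise_sd = 0, seed = NULL, hill = 1,
                               probe_nM = 2) {
  if (kd <= 0) stop("kd must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  f <- .isotherm(concentrations, kd, hill)
  if (noise_sd > 0) {
    f <- pmin(1, pmax(0, f + stats::rnorm(length(f), sd = noise_sd)))
  }
  binding_curve(concentrations, f, probe_nM = probe_nM)
}
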