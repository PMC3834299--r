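#' Fit the dynamic presence model for one strain
#'
#' Reconstructs the dynamic-cutoff idea behind per-array genomotyping: the
#' log-ratio distribution of one hybridization is a mixture whose right
#' component collects the genes present (undiverged) in the test strain. The
#' fit proceeds in five steps:
#'
#' 1. Gaussian kernel density estimate with Silverman's rule-of-thumb
#'    bandwidth on a 512-point grid spanning the data range plus three
#'    bandwidths on each side.
#' 2. The presence-peak mode `m` is the rightmost local maximum of the KDE
#'    whose height is at least `peak_frac` (10%) of the global maximum; the
#'    rightmost-peak rule protects against latching onto the absent-class
#'    mode when deletions are massive. The argmax is refined to sub-grid
#'    accuracy by a parabola fitted to the log density across the peak top.
#' 3. The presence-component scale is estimated from the right half only
#'    (assumed uncontaminated by absent genes) and mirrored:
#'    `sigma^2 = mean((x - m)^2)` over `x >= m`.
#' 4. A scaled Gaussian presence density centred at `m` is divided by the KDE
#'    to give a raw estimated probability of presence: `e(x) = 1` for
#'    `x >= m`, else `min(1, g(x) / max(f(x), eps))`. The Gaussian's width is
#'    the kernel-broadened `sigma^2 + bw^2`, inflated by a few standard
#'    errors of the variance estimate (`width_inflation`), and the ratio is
#'    credited with `se_z` pointwise KDE standard errors — both guards keep
#'    estimation noise around the peak from being read as absence, while the
#'    orders-of-magnitude density drop at the absent class still drives EPP
#'    to zero where it should.
#' 5. Raw density ratios wiggle under the KDE; the final EPP curve is a
#'    least-squares isotonic (non-decreasing) regression of `e` left of the
#'    mode, which makes it monotone in the log ratio without letting isolated
#'    noise dips propagate.
#'
#' @param x Numeric vector of per-gene mean log2 ratios for one strain.
#' @param strain Optional strain label stored in the fit.
#' @param bandwidth Bandwidth rule or value for [stats::density()]. Default
#'   `"nrd0"` (Silverman).
#' @param grid_n Grid size. Default 512.
#' @param peak_frac Minimum relative height for a qualifying mode. Default 0.1.
#' @param eps Density floor in the ratio. Default 1e-12.
#' @param min_n Minimum number of finite log ratios; below this the fit
#'   refuses and an explicit manual cutoff must be used instead. Default 200.
#' @param width_inflation Relative inflation of the numerator variance;
#'   `NULL` (default) uses `max(0.05, 4 * sqrt(2/n_right))`, a few standard
#'   errors of the variance estimate.
#' @param se_z Number of KDE standard errors credited to the density ratio
#'   before it counts as evidence of absence. Default 2.
#' @return Object of class `cgh_presence_fit`: grid, KDE, bandwidth, mode
#'   `mode`, scale `sigma`, and the monotone EPP curve on the grid.
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnorm(1700, 0, 0.3), rnorm(300, -2.5, 0.5))
#' fit <- fit_presence_model(x)
#' glance(fit)
fit_presence_model <- function(x, strain = NULL, bandwidth = "nrd0",
                               grid_n = 512, peak_frac = 0.1,
                               eps = 1e-12, min_n = 200,
                               width_inflation = NULL, se_z = 2) {
  x <- x[is.finite(x)]
  if (length(x) < min_n)
    abort(paste0("Only ", length(x), " finite log ratios (need >= ", min_n,
                 "): too few to fit a presence model; ",
                 "supply an explicit manual cutoff instead."))
  d <- density(x, bw = bandwidth, n = grid_n, cut = 3)
  gx <- d$x; fy <- d$y
  # interior local maxima of the KDE
  peaks <- which(diff(sign(diff(fy))) < 0) + 1L
  peaks <- peaks[fy[peaks] >= peak_frac * max(fy)]
  if (length(peaks) == 0)
    abort("No qualifying density mode found; data look pathologically flat.")
  m_idx <- max(peaks)
  # sub-grid mode refinement: the raw argmax jitters by up to a grid step and
  # biases the mirrored scale estimate; fit a parabola to log f-hat over the
  # upper part of the selected peak and take its vertex
  win <- which(fy >= 0.75 * fy[m_idx])
  run <- split(win, cumsum(c(1, diff(win) != 1)))
  win <- run[[which(vapply(run, function(r) m_idx %in% r, logical(1)))]]
  m <- gx[m_idx]
  if (length(win) >= 3) {
    co <- stats::coef(stats::lm(log(fy[win]) ~ gx[win] + I(gx[win]^2)))
    if (is.finite(co[3]) && co[3] < 0) {
      vertex <- -co[2] / (2 * co[3])
      if (vertex >= min(gx[win]) && vertex <= max(gx[win])) m <- unname(vertex)
    }
  }
  f_m <- approx(gx, fy, xout = m)$y
  right <- x[x >= m]
  sigma <- sqrt(mean((right - m)^2))
  if (!is.finite(sigma) || sigma < 1e-3)
    abort("Presence-peak scale below 1e-3: input is degenerate.")
  # Numerator width: the mirrored-half scale, kernel-broadened to match the
  # KDE in the denominator, then inflated by a few standard errors of the
  # variance estimate. The risk is asymmetric: understating the width makes
  # the density ratio dip spuriously just left of the peak and miscalls
  # clearly-present genes, while a few percent overstatement merely moves
  # the implied cutoff toward the absent class, which sits several sigma
  # away. The EPP transition is then governed by where the absent component
  # actually rises, as intended.
  infl <- width_inflation %||% max(0.05, 4 * sqrt(2 / length(right)))
  s2_num <- (sigma^2 + d$bw^2) * (1 + infl)
  g <- f_m * exp(-(gx - m)^2 / (2 * s2_num))
  # Credit the raw density ratio with its own sampling uncertainty: the KDE
  # pointwise standard error is sqrt(f * R(K) / (n h)) for kernel roughness
  # R(K) = 1/(2 sqrt(pi)); allowing two combined standard errors keeps
  # noise-level dips near the peak from being read as absence, while the
  # orders-of-magnitude plunge at the absent class is untouched.
  rel_se <- sqrt(2 * 0.28209479 / (length(x) * d$bw * pmax(fy, eps)))
  e <- ifelse(gx >= m, 1,
              pmin(1, (g / pmax(fy, eps)) * (1 + se_z * pmin(rel_se, 1))))
  e <- pmax(e, eps)   # EPP stays strictly positive so cutoff -> 0 keeps all
  # monotone regularization: the raw density ratio wiggles with KDE noise; a
  # least-squares isotonic fit left of the mode keeps EPP non-decreasing in
  # the log ratio while averaging noise dips out instead of propagating them
  epp <- e
  left <- which(gx < m)
  if (length(left) > 2) {
    iso <- stats::isoreg(gx[left], e[left])
    epp[left] <- pmin(iso$yf, 1)
  }
  structure(list(strain = strain, grid = gx, density = fy, bw = d$bw,
                 mode = m, sigma = sigma, epp = epp, n = length(x),
                 peak_frac = peak_frac, eps = eps),
            class = "cgh_presence_fit")
}

#' Evaluate the EPP curve of a fit at new log ratios
#'
#' Linear interpolation on the fit grid; values right of the mode get EPP 1,
#' values left of the grid the leftmost (smallest) EPP.
#'
#' @param fit A `cgh_presence_fit`.
#' @param x Numeric log2 ratios.
#' @return Numeric EPP values in `[0, 1]`.
#' @export
predict_epp <- function(fit, x) {
  out <- approx(fit$grid, fit$epp, xout = x, rule = 2)$y
  out[x >= fit$mode] <- 1
  out
}

#' Fit presence models for every strain of an averaged table
#'
#' @param averaged Tibble `probe_id`, `strain`, `log2_ratio` (one row per
#'   probe and strain, from [average_replicates()]).
#' @param ... Passed to [fit_presence_model()].
#' @return Named list of `cgh_presence_fit`, one per strain.
#' @export
fit_presence_models <- function(averaged, ...) {
  split(averaged, averaged$strain) |>
    purrr::imap(function(tab, s) fit_presence_model(tab$log2_ratio,
                                                    strain = s, ...))
}

#' Binarize presence from per-strain EPP fits
#'
#' Applies the presence criterion EPP > `cutoff` (default 0.95) per gene and
#' strain, and records for each strain the implied log-ratio cutoff
#' `x_c = inf{x : EPP(x) > cutoff}`.
#'
#' @param averaged Tibble `probe_id`, `strain`, `log2_ratio`; all strains must
#'   cover the same kept-probe set.
#' @param fits Named list of fits from [fit_presence_models()] (fitted on the
#'   same data by default if `NULL`).
#' @param cutoff EPP presence cutoff in (0, 1). Default 0.95.
#' @return Object of class `cgh_presence`: integer `presence` matrix (genes x
#'   strains), numeric `epp` matrix, `cutoff`, per-strain tibble `strain_info`
#'   (mode, sigma, implied cutoff `x_c`, present count).
#' @export
call_presence <- function(averaged, fits = NULL, cutoff = 0.95) {
  if (cutoff <= 0 || cutoff >= 1)
    abort("`cutoff` must lie strictly between 0 and 1.")
  if (is.null(fits)) fits <- fit_presence_models(averaged)
  strains <- names(fits)
  wide <- averaged |>
    dplyr::select("probe_id", "strain", "log2_ratio") |>
    tidyr::pivot_wider(names_from = "strain", values_from = "log2_ratio")
  genes <- wide$probe_id
  epp <- matrix(NA_real_, nrow = length(genes), ncol = length(strains),
                dimnames = list(genes, strains))
  for (s in strains) {
    xs <- wide[[s]]
    ok <- is.finite(xs)
    epp[ok, s] <- predict_epp(fits[[s]], xs[ok])
  }
  presence <- (epp > cutoff) * 1L
  presence[is.na(presence)] <- 0L
  info <- purrr::map_dfr(strains, function(s) {
    f <- fits[[s]]
    above <- f$epp > cutoff
    x_c <- if (any(above)) f$grid[which(above)[1]] else Inf
    tibble(strain = s, mode = f$mode, sigma = f$sigma, x_c = x_c,
           n_present = sum(presence[, s]))
  })
  structure(list(presence = presence, epp = epp, cutoff = cutoff,
                 strain_info = info, fits = fits),
            class = "cgh_presence")
}

#' @export
print.cgh_presence_fit <- function(x, ...) {
  cat("<cgh_presence_fit>", if (!is.null(x$strain)) x$strain else "",
      sprintf(" n=%d mode=%.3f sigma=%.3f bw=%.4f\n", x$n, x$mode, x$sigma,
              x$bw), sep = "")
  invisible(x)
}

#' @export
print.cgh_presence <- function(x, ...) {
  cat("<cgh_presence> ", nrow(x$presence), " genes x ", ncol(x$presence),
      " strains, cutoff EPP > ", x$cutoff, "\n", sep = "")
  print(x$strain_info)
  invisible(x)
}

#' @rdname fit_presence_model
#' @param x A `cgh_presence_fit`.
#' @param ... Unused.
#' @method glance cgh_presence_fit
#' @export
glance.cgh_presence_fit <- function(x, ...) {
  tibble(strain = x$strain %||% NA_character_, n = x$n, bandwidth = x$bw,
         mode = x$mode, sigma = x$sigma)
}

#' @rdname fit_presence_model
#' @method tidy cgh_presence_fit
#' @export
tidy.cgh_presence_fit <- function(x, ...) {
  tibble(log2_ratio = x$grid, density = x$density, epp = x$epp)
}

#' Tidy a presence-call object into a long tibble
#'
#' @param x A `cgh_presence`.
#' @param ... Unused.
#' @return Tibble `probe_id`, `strain`, `epp`, `present`.
#' @method tidy cgh_presence
#' @export
tidy.cgh_presence <- function(x, ...) {
  as_tibble(as.data.frame.table(x$epp, responseName = "epp",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(probe_id = "Var1", strain = "Var2") |>
    dplyr::mutate(present = as.integer(
      x$presence[cbind(.data$probe_id, .data$strain)]))
}

#' Diagnostic plot of a presence-model fit
#'
#' Overlays the KDE, the scaled presence component implied by the mirrored
#' right-half fit, and the EPP curve; the dashed line marks the implied
#' log-ratio cutoff at EPP = 0.95.
#'
#' @param object A `cgh_presence_fit`.
#' @param cutoff EPP cutoff drawn as reference. Default 0.95.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cgh_presence_fit
#' @export
autoplot.cgh_presence_fit <- function(object, cutoff = 0.95, ...) {
  dat <- tidy(object)
  scale <- max(dat$density)
  x_c <- dat$log2_ratio[which(dat$epp > cutoff)[1]]
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$log2_ratio)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$density), alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$epp * scale),
                       colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$mode, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = x_c, linetype = "dashed") +
    ggplot2::scale_y_continuous(
      "density", sec.axis = ggplot2::sec_axis(~ . / scale, name = "EPP")) +
    ggplot2::labs(x = "log2(test / reference)",
                  title = object$strain %||% "presence model")
}
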