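#' One load-indentation measurement
#'
#' @param indentation_um recorded indentation axis, micrometres; strictly
#'   increasing on the loading segment.
#' @param load_n load, newtons; same length as `indentation_um`, >= 10
#'   samples.
#' @param tip_radius_um spherical tip radius (> 0).
#' @param cantilever_stiffness N/m (metadata).
#' @param position optional `(x, y)` um position on the sample.
#' @return object of class `indentation_curve`.
#' @export
indentation_curve <- function(indentation_um, load_n, tip_radius_um = 25,
                              cantilever_stiffness = 0.5, position = NULL) {
  if (length(indentation_um) != length(load_n) || length(load_n) < 10)
    oc_abort("indentation and load must have equal length >= 10",
             "invalid_input")
  if (tip_radius_um <= 0) oc_abort("tip radius must be > 0", "invalid_input")
  if (any(diff(indentation_um) <= 0))
    oc_abort("indentation must be strictly increasing", "invalid_input")
  structure(list(indentation_um = as.numeric(indentation_um),
                 load_n = as.numeric(load_n),
                 tip_radius_um = tip_radius_um,
                 cantilever_stiffness = cantilever_stiffness,
                 position = position),
            class = "indentation_curve")
}

#' Detect the contact point of an indentation curve
#'
#' The leading `baseline_frac` of samples is treated as pre-contact baseline;
#' its level and spread are estimated robustly (median and MAD). A coarse
#' contact estimate is the last sample before the load first stays above
#' `baseline + k * spread` for `min_run` consecutive samples; it is then
#' refined by the Hertzian linearization `F^(2/3) = const * (delta - delta0)`
#' fitted over the upper part of the loading curve, whose intercept locates
#' the contact point to sub-sample precision (exactly, for noiseless
#' power-law data).
#'
#' @param curve an [indentation_curve()].
#' @param baseline_frac fraction of leading samples forming the baseline.
#' @param k threshold in baseline SD units.
#' @param min_run consecutive above-threshold samples required.
#' @return contact offset in um: subtracting it re-zeroes the indentation
#'   axis at contact.
#' @export
detect_contact_point <- function(curve, baseline_frac = 0.2, k = 5,
                                 min_run = 3L) {
  n <- length(curve$load_n)
  nb <- max(3L, floor(baseline_frac * n))
  base <- curve$load_n[seq_len(nb)]
  centre <- median(base)
  spread <- mad(base)
  if (spread == 0) spread <- sd(base)
  if (!is.finite(spread) || spread == 0)
    spread <- 1e-4 * max(abs(curve$load_n - centre), .Machine$double.eps)
  thr <- centre + k * spread
  above <- curve$load_n > thr
  run <- 0L
  hit <- NA_integer_
  for (i in seq_len(n)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= min_run) { hit <- i - min_run + 1L; break }
  }
  if (is.na(hit))
    oc_abort("no contact found: load never leaves the baseline",
             "contact_not_found")
  coarse <- curve$indentation_um[max(hit - 1L, 1L)]

  # refine: F^(2/3) is linear in indentation for Hertzian contact; its
  # x-intercept is the contact point, fitted over the high-load region where
  # the relative noise is small. Iterated because the baseline level must be
  # re-estimated from the samples before the current contact estimate (the
  # initial fixed-fraction window may overlap the contact rise on curves
  # with little pre-contact travel).
  step <- median(diff(curve$indentation_um))
  est <- coarse
  for (iter in 1:3) {
    pre <- curve$load_n[curve$indentation_um < est]
    c2 <- if (length(pre) >= 3) median(pre) else 0
    load0 <- curve$load_n - c2
    sel <- which(curve$indentation_um >= est & load0 > 0.1 * max(load0))
    if (length(sel) < 5) break
    fit <- stats::lm.fit(cbind(1, curve$indentation_um[sel]),
                         load0[sel]^(2 / 3))
    b <- fit$coefficients[2]
    if (!is.finite(b) || b <= 0) break
    refined <- unname(-fit$coefficients[1] / b)
    # the true contact cannot lie later than the threshold crossing (plus a
    # small margin), nor before the recorded sweep
    if (!is.finite(refined) || refined > coarse + 5 * step ||
        refined < min(curve$indentation_um) - 5 * step) break
    done <- abs(refined - est) < step / 10
    est <- refined
    if (done) break
  }
  est
}

#' Fit the Hertz model over a fixed indentation window
#'
#' Linear least squares of load against `delta^(3/2)` over samples whose
#' (re-zeroed) indentation lies in `window` — the closed-form estimate of the
#' Young's modulus for the sphere-on-half-space contact law, with no
#' initialization choices. The default window of 1-4 um matches the
#' measurement protocol for on-chip hydrogels.
#'
#' @param curve an [indentation_curve()], re-zeroed so indentation 0 is the
#'   contact point (see [detect_contact_point()]).
#' @param nu Poisson ratio (default 0.5, incompressible hydrogel).
#' @param window `(lo, hi)` indentation interval in um; the curve must cover
#'   it.
#' @return list: `E_pa` (> 0), `residual_n` (RMS load misfit over the
#'   window), `n_samples`.
#' @export
hertz_fit <- function(curve, nu = 0.5, window = c(1, 4)) {
  if (nu < 0 || nu > 0.5 + 1e-12)
    oc_abort("`nu` must be in [0, 0.5]", "invalid_input")
  d <- curve$indentation_um
  if (max(d) < window[2] || min(d) > window[1])
    oc_abort(sprintf(
      "curve spans [%.3g, %.3g] um; does not cover the fit window [%g, %g]",
      min(d), max(d), window[1], window[2]), "insufficient_range")
  sel <- d >= window[1] & d <= window[2]
  if (sum(sel) < 3)
    oc_abort("fewer than 3 samples inside the fit window",
             "insufficient_range")
  x <- (d[sel] * 1e-6)^1.5
  y <- curve$load_n[sel]
  slope <- sum(x * y) / sum(x * x)
  E <- slope * 0.75 * (1 - nu^2) / sqrt(curve$tip_radius_um * 1e-6)
  if (!is.finite(E) || E <= 0)
    oc_abort("fitted modulus is not positive", "fit_failure")
  list(E_pa = E, residual_n = sqrt(mean((y - slope * x)^2)),
       n_samples = sum(sel))
}

#' Fit an array of curves into an elasticity map
#'
#' Runs contact detection and the Hertz fit on every curve. Curves failing
#' any stage are kept in the map flagged `accepted = FALSE` with the failure
#' reason — never silently dropped. Entry order follows input order.
#'
#' @param curves list of [indentation_curve()]s.
#' @param nu Poisson ratio.
#' @param window fit window, um.
#' @param baseline_frac,k contact-detection parameters
#'   (see [detect_contact_point()]).
#' @return data frame of class `elasticity_map`: `curve_id`, `x_um`, `y_um`,
#'   `E_pa`, `residual_n`, `accepted`, `reason`.
#' @export
fit_array <- function(curves, nu = 0.5, window = c(1, 4),
                      baseline_frac = 0.2, k = 5) {
  if (length(curves) < 1) oc_abort("need >= 1 curve", "invalid_input")
  rows <- lapply(seq_along(curves), function(i) {
    crv <- curves[[i]]
    pos <- crv$position %||% c(NA_real_, NA_real_)
    res <- tryCatch({
      off <- detect_contact_point(crv, baseline_frac, k)
      zeroed <- crv
      zeroed$indentation_um <- crv$indentation_um - off
      keep <- zeroed$indentation_um > 0
      if (sum(keep) >= 10) {
        zeroed$indentation_um <- zeroed$indentation_um[keep]
        zeroed$load_n <- zeroed$load_n[keep]
      }
      fit <- hertz_fit(zeroed, nu, window)
      data.frame(curve_id = i, x_um = pos[1], y_um = pos[2],
                 E_pa = fit$E_pa, residual_n = fit$residual_n,
                 accepted = TRUE, reason = "", stringsAsFactors = FALSE)
    }, osteochip_error = function(e) {
      data.frame(curve_id = i, x_um = pos[1], y_um = pos[2],
                 E_pa = NA_real_, residual_n = NA_real_, accepted = FALSE,
                 reason = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("elasticity_map", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize an elasticity map by group
#'
#' Mean, median, SD and n of the Young's modulus per group, over accepted
#' entries only (flagged entries never contribute).
#'
#' @param map an [fit_array()] result.
#' @param groups label per map entry (e.g. compartment), recycled if length 1.
#' @return data frame: `group`, `mean_pa`, `median_pa`, `sd_pa`, `n`.
#' @export
summarize_map <- function(map, groups = "all") {
  if (length(groups) == 1L) groups <- rep(groups, nrow(map))
  if (length(groups) != nrow(map))
    oc_abort("`groups` must match the number of map entries", "invalid_input")
  out <- lapply(unique(groups), function(g) {
    e <- map$E_pa[groups == g & map$accepted]
    if (length(e) == 0)
      oc_abort(sprintf("group '%s' has no accepted entries", g),
               "undefined_summary")
    data.frame(group = g, mean_pa = mean(e), median_pa = median(e),
               sd_pa = if (length(e) > 1) sd(e) else 0, n = length(e),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Read / write indentation curves in long CSV format
#'
#' Columns: `curve_id`, `position_x_um`, `position_y_um`, `indentation_um`
#' and a load column — `load_n` (newtons) or `load_nn` (nanonewtons), which
#' is converted on read.
#'
#' @param curves list of [indentation_curve()]s.
#' @param path CSV file.
#' @param tip_radius_um,cantilever_stiffness probe metadata applied on read.
#' @return `write_curves_csv` returns `path` invisibly; `read_curves_csv`
#'   returns a list of curves.
#' @export
write_curves_csv <- function(curves, path) {
  rows <- lapply(seq_along(curves), function(i) {
    crv <- curves[[i]]
    pos <- crv$position %||% c(NA_real_, NA_real_)
    data.frame(curve_id = i, position_x_um = pos[1], position_y_um = pos[2],
               indentation_um = crv$indentation_um, load_n = crv$load_n)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path, tip_radius_um = 25,
                            cantilever_stiffness = 0.5) {
  if (!file.exists(path))
    oc_abort(sprintf("file not found: %s", path), "missing_file")
  tab <- read.csv(path)
  if (!"load_n" %in% names(tab)) {
    if ("load_nn" %in% names(tab)) tab$load_n <- tab$load_nn * 1e-9
    else oc_abort("need a `load_n` or `load_nn` column", "invalid_input")
  }
  lapply(split(tab, tab$curve_id), function(d) {
    pos <- c(d$position_x_um[1], d$position_y_um[1])
    if (all(is.na(pos))) pos <- NULL
    indentation_curve(d$indentation_um, d$load_n,
                      tip_radius_um = tip_radius_um,
                      cantilever_stiffness = cantilever_stiffness,
                      position = pos)
  })
}
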