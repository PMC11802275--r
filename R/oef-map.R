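# Vein-based OEF mapping.  Veins carry more deoxyhemoglobin and hence
# higher magnetic susceptibility than surrounding tissue; within each
# local window, voxels above mean + k*SD of the in-mask susceptibility are
# taken as venous, the vein/tissue susceptibility difference is converted
# to an oxygen extraction fraction by
#
#     OEF = (delta_chi * P_v) / (delta_chi_do * Hct)
#
# and a sliding window assembles a whole-brain OEF map.

#' Physiological constants of the OEF equation
#'
#' @param delta_chi_do susceptibility difference between fully
#'   deoxygenated and fully oxygenated blood per unit hematocrit.  Default
#'   `4*pi*0.18` ppm (SI), the exact SI equivalent of the literature CGS
#'   value `1.8e-7`; in CGS mode the default is `1.8e-7` itself.  The two
#'   unit systems give identical OEF when the susceptibility volume is
#'   converted consistently (`chi_SI = 4*pi*chi_CGS`).
#' @param hct hematocrit fraction, default 0.45 (literature value; the
#'   study design uses a global constant rather than per-subject bloods).
#' @param pv partial-volume correction factor scaling the measured
#'   vein/tissue contrast to the intravascular value; default 6.0.
#' @param unit_system `"SI_ppm"` (susceptibilities in ppm, SI) or
#'   `"CGS"` (dimensionless CGS units).
#' @return object of class `oef_params`.
#' @export
oef_params <- function(delta_chi_do = NULL, hct = 0.45, pv = 6.0,
                       unit_system = c("SI_ppm", "CGS")) {
  unit_system <- match.arg(unit_system)
  if (is.null(delta_chi_do))
    delta_chi_do <- if (unit_system == "SI_ppm") 4 * pi * 0.18 else 1.8e-7
  stopifnot(delta_chi_do > 0, hct > 0, hct < 1, pv >= 1)
  structure(list(delta_chi_do = delta_chi_do, hct = hct, pv = pv,
                 unit_system = unit_system),
            class = "oef_params")
}

#' Sliding-window (VOI) geometry and vein-detection settings
#'
#' @param voi_shape_voxels window dimensions, default `c(64, 64, 30)`.
#' @param stride_voxels window step per axis; default half the window.
#' @param threshold_sd_multiplier vein threshold is
#'   `mean + multiplier * SD` of in-mask window susceptibility (one-sided
#'   upper: veins are paramagnetic relative to tissue).  Default 2.
#' @param min_vein_voxels windows detecting fewer vein voxels are flagged
#'   undefined instead of yielding an order-statistic-dominated contrast.
#' @param min_mask_voxels minimum in-mask voxels for a window to be
#'   evaluated at all.
#' @return object of class `voi_grid`.
#' @export
voi_grid <- function(voi_shape_voxels = c(64, 64, 30),
                     stride_voxels = NULL,
                     threshold_sd_multiplier = 2.0,
                     min_vein_voxels = 5L,
                     min_mask_voxels = 27L) {
  voi_shape_voxels <- as.integer(voi_shape_voxels)
  if (is.null(stride_voxels))
    stride_voxels <- pmax(1L, voi_shape_voxels %/% 2L)
  stride_voxels <- as.integer(stride_voxels)
  stopifnot(length(voi_shape_voxels) == 3L, all(voi_shape_voxels >= 4L),
            all(stride_voxels >= 1L), all(stride_voxels <= voi_shape_voxels),
            threshold_sd_multiplier > 0, min_vein_voxels >= 1)
  structure(list(voi_shape_voxels = voi_shape_voxels,
                 stride_voxels = stride_voxels,
                 threshold_sd_multiplier = threshold_sd_multiplier,
                 min_vein_voxels = as.integer(min_vein_voxels),
                 min_mask_voxels = as.integer(min_mask_voxels)),
            class = "voi_grid")
}

# Window start positions along one axis: regular stride plus a final
# window flush with the end, clipped for volumes smaller than the window.
.window_starts <- function(n, w, s) {
  if (n <= w) return(1L)
  last <- n - w + 1L
  unique(c(seq.int(1L, last, by = s), last))
}

#' Detect venous voxels within a VOI
#'
#' Venous voxels are in-mask voxels with susceptibility above
#' `mean + multiplier * SD`, both computed over the in-mask voxels of the
#' VOI.  Degenerate VOIs (too few in-mask voxels, or SD below machine
#' tolerance) yield an undefined result, not an error.
#'
#' @param chi 3D susceptibility array.
#' @param mask logical brain mask (same grid).
#' @param bounds list of three integer `(lo, hi)` pairs delimiting the VOI.
#' @param grid [voi_grid()].
#' @return list with `vein` (logical array over the VOI, or `NULL`),
#'   `defined` (logical), `reason` (character when undefined).
#' @export
detect_veins <- function(chi, mask, bounds, grid = voi_grid()) {
  ix <- lapply(bounds, function(b) seq.int(b[1L], b[2L]))
  sub <- chi[ix[[1L]], ix[[2L]], ix[[3L]], drop = FALSE]
  m <- mask[ix[[1L]], ix[[2L]], ix[[3L]], drop = FALSE]
  if (sum(m) < grid$min_mask_voxels)
    return(list(vein = NULL, defined = FALSE, reason = "voi_outside_mask"))
  vals <- sub[m]
  mu <- mean(vals)
  sdv <- stats::sd(vals)
  if (!is.finite(sdv) || sdv < 1e-12)
    return(list(vein = array(FALSE, dim = dim(sub)), defined = TRUE,
                reason = NA_character_))
  vein <- m & (sub > mu + grid$threshold_sd_multiplier * sdv)
  list(vein = vein, defined = TRUE, reason = NA_character_)
}

#' Vein/tissue susceptibility difference within a VOI
#'
#' `delta_chi = mean(chi over vein voxels) - mean(chi over non-vein
#' in-mask voxels)`.  Shift-invariant by construction.  Undefined (NA,
#' with a reason) when the vein mask is empty or no surrounding tissue
#' remains.
#'
#' @inheritParams detect_veins
#' @param vein logical vein mask over the VOI (from [detect_veins()]).
#' @param min_tissue_voxels minimum non-vein in-mask voxels required.
#' @return list with `delta_chi` (numeric or NA), `n_vein`, `n_tissue`,
#'   `reason`.
#' @export
estimate_delta_chi <- function(chi, mask, bounds, vein,
                               min_tissue_voxels = 27L) {
  ix <- lapply(bounds, function(b) seq.int(b[1L], b[2L]))
  sub <- chi[ix[[1L]], ix[[2L]], ix[[3L]], drop = FALSE]
  m <- mask[ix[[1L]], ix[[2L]], ix[[3L]], drop = FALSE]
  if (is.null(vein) || !any(vein))
    return(list(delta_chi = NA_real_, n_vein = 0L, n_tissue = sum(m),
                reason = "no_veins"))
  tissue <- m & !vein
  if (sum(tissue) < min_tissue_voxels)
    return(list(delta_chi = NA_real_, n_vein = sum(vein),
                n_tissue = sum(tissue), reason = "no_surrounding_tissue"))
  list(delta_chi = mean(sub[vein]) - mean(sub[tissue]),
       n_vein = sum(vein), n_tissue = sum(tissue), reason = NA_character_)
}

#' Convert a susceptibility difference to an oxygen extraction fraction
#'
#' `OEF = delta_chi * P_v / (delta_chi_do * Hct)`.  No clamping: values
#' outside `[0, 1]` are returned as-is and flagged downstream.
#'
#' @param delta_chi vein/tissue susceptibility difference, in the unit
#'   system of `params`.
#' @param params [oef_params()].
#' @return OEF as a dimensionless fraction (NA for non-finite input).
#' @export
oef_from_delta_chi <- function(delta_chi, params = oef_params()) {
  out <- delta_chi * params$pv / (params$delta_chi_do * params$hct)
  out[!is.finite(out)] <- NA_real_
  out
}

#' Whole-brain OEF map by sliding window
#'
#' Steps windows of the VOI shape across the volume, computes each
#' window's scalar OEF (vein detection, susceptibility contrast, OEF
#' conversion), and assigns it to all in-mask voxels of the window.
#' Voxels covered by several defined windows get the unweighted mean of
#' their values; voxels with no defined window are `NA`.
#'
#' @param chi 3D susceptibility array.
#' @param mask logical brain mask.
#' @param grid [voi_grid()].
#' @param params [oef_params()].
#' @param keep_negative keep windows with negative susceptibility
#'   contrast (default `FALSE`: flagged undefined, since a vein less
#'   paramagnetic than tissue contradicts the detection physics).
#' @return object of class `oef_map`: list with `values` (3D array, OEF
#'   fraction, NA where undefined), `window_count` (3D integer array of
#'   contributing windows), `windows` (per-window bookkeeping data.frame),
#'   `grid`, `params`.
#' @export
sliding_window_oef <- function(chi, mask, grid = voi_grid(),
                               params = oef_params(),
                               keep_negative = FALSE) {
  d <- dim(chi)
  w <- pmin(grid$voi_shape_voxels, d)
  sx <- .window_starts(d[1L], w[1L], grid$stride_voxels[1L])
  sy <- .window_starts(d[2L], w[2L], grid$stride_voxels[2L])
  sz <- .window_starts(d[3L], w[3L], grid$stride_voxels[3L])
  acc <- array(0, dim = d)
  cnt <- array(0L, dim = d)
  rows <- list()
  for (x0 in sx) for (y0 in sy) for (z0 in sz) {
    bounds <- list(c(x0, x0 + w[1L] - 1L), c(y0, y0 + w[2L] - 1L),
                   c(z0, z0 + w[3L] - 1L))
    det <- detect_veins(chi, mask, bounds, grid)
    oef <- NA_real_
    reason <- det$reason
    if (det$defined) {
      if (is.null(det$vein) || sum(det$vein) < grid$min_vein_voxels) {
        reason <- "too_few_vein_voxels"
      } else {
        est <- estimate_delta_chi(chi, mask, bounds, det$vein)
        if (is.na(est$delta_chi)) {
          reason <- est$reason
        } else if (est$delta_chi < 0 && !keep_negative) {
          reason <- "negative_delta_chi"
        } else {
          oef <- oef_from_delta_chi(est$delta_chi, params)
        }
      }
    }
    rows[[length(rows) + 1L]] <- data.frame(
      x0 = x0, y0 = y0, z0 = z0, oef = oef,
      reason = if (is.na(oef)) reason else NA_character_,
      stringsAsFactors = FALSE)
    if (!is.na(oef)) {
      ix <- seq.int(x0, x0 + w[1L] - 1L)
      iy <- seq.int(y0, y0 + w[2L] - 1L)
      iz <- seq.int(z0, z0 + w[3L] - 1L)
      inm <- mask[ix, iy, iz, drop = FALSE]
      acc[ix, iy, iz][inm] <- acc[ix, iy, iz][inm] + oef
      cnt[ix, iy, iz][inm] <- cnt[ix, iy, iz][inm] + 1L
    }
  }
  values <- acc / ifelse(cnt > 0L, cnt, NA_integer_)
  values[!mask] <- NA_real_
  windows <- do.call(rbind, rows)
  if (all(is.na(windows$oef)))
    warning("no window yielded a defined OEF; map is all-undefined")
  structure(list(values = values, window_count = cnt, windows = windows,
                 grid = grid, params = params),
            class = "oef_map")
}

#' Regional mean OEF against an integer label volume
#'
#' @param map an `oef_map` or a 3D array of OEF fractions with NA for
#'   undefined voxels.
#' @param labels integer 3D label volume on the same grid (0 = unlabeled).
#' @param names optional data.frame with columns `label`, `region` mapping
#'   label codes to region names.
#' @param percent report means in percent (default, as regional OEF tables
#'   conventionally print) rather than as fractions.
#' @return data.frame with columns `label`, `region`, `mean_oef`,
#'   `n_defined`.  Labels present in the volume but with zero defined
#'   voxels are omitted with a warning.
#' @export
roi_means <- function(map, labels, names = NULL, percent = TRUE) {
  values <- if (inherits(map, "oef_map")) map$values else map
  if (!identical(dim(values), dim(labels)))
    stop("label volume grid (", paste(dim(labels), collapse = "x"),
         ") does not match map grid (", paste(dim(values), collapse = "x"), ")")
  codes <- sort(unique(labels[labels > 0]))
  out <- list()
  for (code in codes) {
    sel <- labels == code & !is.na(values)
    n <- sum(sel)
    if (n == 0L) {
      warning("label ", code, " has no defined OEF voxels; omitted")
      next
    }
    region <- as.character(code)
    if (!is.null(names)) {
      hit <- match(code, names$label)
      if (!is.na(hit)) region <- names$region[hit]
    }
    out[[length(out) + 1L]] <- data.frame(
      label = code, region = region,
      mean_oef = mean(values[sel]) * if (percent) 100 else 1,
      n_defined = n, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(label = integer(), region = character(),
                      mean_oef = numeric(), n_defined = integer()))
  do.call(rbind, out)
}

#' Rasterization-derived partial-volume factors of a phantom
#'
#' For each recorded vein, the ratio of the intended intravascular
#' susceptibility offset to the mean truth-susceptibility offset actually
#' present over the recorded vein voxels (relative to non-vein in-mask
#' tissue).  A geometric calibration of the phantom's rasterization: 1 for
#' binary centre-distance rasterization.  Never derived from the
#' estimator's own windowed contrast.
#'
#' @param phantom a `susceptibility_phantom` with at least one vein.
#' @return numeric vector, one factor per vein record.
#' @export
rasterization_pv <- function(phantom) {
  stopifnot(inherits(phantom, "susceptibility_phantom"),
            length(phantom$vein_records) > 0)
  all_vein <- unique(unlist(lapply(phantom$vein_records, `[[`, "voxels")))
  tissue_ix <- setdiff(which(phantom$brain_mask), all_vein)
  tissue_mean <- mean(phantom$chi_ppm[tissue_ix])
  vapply(phantom$vein_records, function(rec) {
    measured <- mean(phantom$chi_ppm[rec$voxels]) - tissue_mean
    rec$chi_offset_ppm / measured
  }, numeric(1))
}
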