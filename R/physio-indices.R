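#' Relative water content
#'
#' Computes RWC as a percentage. The study's formula,
#' \eqn{RWC = 100 (FW - DW) / (TW - FW)}, normalises the water content
#' by the water deficit at sampling rather than by the conventional
#' total water capacity \eqn{TW - DW}; both are provided, with the
#' study's form as the default so results are comparable with its
#' reported 62.5-80% series.
#'
#' @param fw,dw,tw Fresh, dry and turgid weights (g); vectorised.
#' @param formula \code{"printed"} (denominator TW - FW, the default) or
#'   \code{"standard"} (denominator TW - DW).
#' @return RWC in percent. Inputs with DW > FW yield a negative result
#'   with a warning (flagged, not clipped).
#' @export
rwc <- function(fw, dw, tw, formula = c("printed", "standard")) {
  formula <- match.arg(formula)
  stopifnot(all(fw > 0), all(dw > 0), all(tw > 0))
  den <- if (formula == "printed") tw - fw else tw - dw
  if (any(den == 0)) {
    stop(if (formula == "printed") "TW equals FW" else "TW equals DW",
         ": RWC denominator is zero", call. = FALSE)
  }
  if (formula == "printed" && any(tw < fw)) {
    stop("TW < FW: turgid weight below fresh weight", call. = FALSE)
  }
  out <- 100 * (fw - dw) / den
  if (any(dw > fw)) warning("DW > FW for some samples: negative RWC returned")
  out
}

#' Leaf succulence
#'
#' Fresh weight per unit leaf area (g cm-2), a proxy for water-storing
#' tissue thickness.
#'
#' @param fw Fresh weight (g).
#' @param area Leaf area (cm^2, > 0).
#' @return Succulence in g cm-2.
#' @export
succulence <- function(fw, area) {
  stopifnot(all(fw >= 0))
  if (any(area <= 0)) stop("leaf area must be positive", call. = FALSE)
  fw / area
}

#' Malondialdehyde concentration from TBARS absorbances
#'
#' Applies the assay calibration \eqn{MDA (\mu mol\,L^{-1}) =
#' 6.45\,OD_{532} - 0.56\,OD_{450}}. Negative results (possible for
#' pigment-dominated extracts) are returned with a warning, never
#' clipped.
#'
#' @param od532,od450 Absorbances at 532 and 450 nm (>= 0); vectorised.
#' @return Concentration in umol L-1.
#' @export
mda_concentration <- function(od532, od450) {
  stopifnot(all(od532 >= 0), all(od450 >= 0))
  out <- 6.45 * od532 - 0.56 * od450
  if (any(out < 0)) warning("negative MDA concentration returned (flagged, not clipped)")
  out
}

#' Convert MDA concentration to tissue content
#'
#' Bridges the assay's umol/L readout to nmol per gram fresh weight
#' through the extraction bookkeeping: the reaction-mix concentration
#' times the assay volume gives moles in the aliquot, scaled up by
#' extract/aliquot to the whole extract, divided by the tissue mass.
#' Defaults follow the protocol: 0.2 g tissue in 3 mL TCA, 2 mL
#' supernatant + 2 mL TBA (4 mL assay volume).
#'
#' @param concentration MDA in umol L-1 (from [mda_concentration()]).
#' @param tissue_mass Tissue fresh weight (g, default 0.2).
#' @param extract_volume Extraction volume (mL, default 3).
#' @param aliquot_volume Supernatant aliquot carried into the assay
#'   (mL, default 2; must not exceed \code{extract_volume}).
#' @param assay_volume Final assay volume (mL, default 4).
#' @return MDA content in nmol g-1 fresh weight.
#' @export
mda_per_gram <- function(concentration, tissue_mass = 0.2,
                         extract_volume = 3, aliquot_volume = 2,
                         assay_volume = 4) {
  stopifnot(all(tissue_mass > 0), extract_volume > 0, aliquot_volume > 0,
            assay_volume > 0)
  if (aliquot_volume > extract_volume) {
    stop("aliquot volume exceeds extract volume", call. = FALSE)
  }
  concentration * (assay_volume / 1000) * (extract_volume / aliquot_volume) /
    tissue_mass * 1000
}

#' Daily index series with means and standard errors
#'
#' Applies the three physiological indices row-wise to a raw sample
#' table (so each replicate's index is computed from its own raw
#' measurements before aggregation) and summarises per day and group.
#' Rows missing the fields of an index contribute to the other indices
#' but are omitted, with a message, from that one.
#'
#' @param samples Data frame with columns \code{day}, \code{group},
#'   \code{fw_g}, \code{tw_g}, \code{dw_g}, \code{area_cm2},
#'   \code{od532}, \code{od450}, \code{tissue_g} (the last defaulting
#'   to 0.2 when absent).
#' @param rwc_formula Passed to [rwc()].
#' @return Long data frame: \code{day}, \code{group}, \code{index}
#'   (\code{"rwc"}, \code{"succulence"}, \code{"mda"}), \code{mean},
#'   \code{se}, \code{n}. Attribute \code{rwc_formula} records the
#'   denominator convention used.
#' @export
index_series <- function(samples, rwc_formula = c("printed", "standard")) {
  rwc_formula <- match.arg(rwc_formula)
  stopifnot(is.data.frame(samples), all(c("day", "group") %in% names(samples)))
  s <- samples
  if (is.null(s$tissue_g)) s$tissue_g <- 0.2

  per_row <- function(cols, f) {
    ok <- Reduce(`&`, lapply(cols, function(cl) !is.null(s[[cl]]) & !is.na(s[[cl]])))
    if (!length(ok) || !any(ok)) return(NULL)
    if (any(!ok)) message(sum(!ok), " rows lack fields for an index; omitted")
    v <- f(s[ok, , drop = FALSE])
    data.frame(day = s$day[ok], group = s$group[ok], value = v)
  }
  parts <- list(
    rwc = per_row(c("fw_g", "tw_g", "dw_g"),
                  function(d) rwc(d$fw_g, d$dw_g, d$tw_g, formula = rwc_formula)),
    succulence = per_row(c("fw_g", "area_cm2"),
                         function(d) succulence(d$fw_g, d$area_cm2)),
    mda = per_row(c("od532", "od450", "tissue_g"),
                  function(d) mda_per_gram(mda_concentration(d$od532, d$od450),
                                           tissue_mass = d$tissue_g)))
  out <- do.call(rbind, lapply(names(parts), function(nm) {
    p <- parts[[nm]]
    if (is.null(p)) return(NULL)
    agg <- dplyr::summarise(
      dplyr::group_by(p, .data$day, .data$group),
      mean = mean(.data$value),
      se = if (dplyr::n() > 1) stats::sd(.data$value) / sqrt(dplyr::n()) else 0,
      n = dplyr::n(), .groups = "drop")
    cbind(index = nm, as.data.frame(agg))[, c("day", "group", "index", "mean", "se", "n")]
  }))
  rownames(out) <- NULL
  attr(out, "rwc_formula") <- rwc_formula
  out
}
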