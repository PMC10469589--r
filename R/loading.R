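# Pool molarity and sequencer loading dilution.

#' Convert pool mass concentration to molarity
#'
#' Standard dsDNA conversion at 660 g/mol per base pair:
#' `nM = ng_per_ul * 1e6 / (660 * mean_fragment_bp)`.
#'
#' @param mass_conc_ng_ul Pool concentration in ng/µL (> 0).
#' @param mean_fragment_bp Mean library fragment length in bp (> 0), from a
#'   fragment-length distribution analysis of the pool.
#' @return Molarity in nM.
#' @export
molarity_nM <- function(mass_conc_ng_ul, mean_fragment_bp) {
  stopifnot(mass_conc_ng_ul > 0, mean_fragment_bp > 0)
  mass_conc_ng_ul * 1e6 / (660 * mean_fragment_bp)
}

#' Compute a sequencer loading dilution
#'
#' Dilutes the pool to the loading concentration — by default 90 pM in
#' 20 µL, the iSeq loading spec. Warns when the required pool volume falls
#' below a pipettable threshold and suggests an intermediate dilution.
#'
#' @param pool_nM Pool molarity (nM).
#' @param target_pM Loading concentration (pM), default 90.
#' @param final_volume_ul Loading volume (µL), default 20.
#' @param min_pipettable_ul Warn below this pool volume (µL), default 0.5.
#' @return Object of class `dilution_plan`: list with `pool_volume_ul`,
#'   `diluent_volume_ul`, `final_conc_pm`, `final_volume_ul`.
#' @export
dilution_plan <- function(pool_nM, target_pM = 90, final_volume_ul = 20,
                          min_pipettable_ul = 0.5) {
  stopifnot(pool_nM > 0, target_pM > 0, final_volume_ul > 0)
  if (pool_nM * 1000 < target_pM) {
    stop(sprintf(
      "pool at %.4g nM is below the %.4g pM target; load neat or re-pool",
      pool_nM, target_pM), call. = FALSE)
  }
  pool_vol <- final_volume_ul * target_pM / (1000 * pool_nM)
  if (pool_vol < min_pipettable_ul) {
    warning(sprintf(
      paste0("pool volume %.3g µL is below the %.2g µL pipettable minimum; ",
             "consider an intermediate %dx dilution"),
      pool_vol, min_pipettable_ul,
      ceiling(min_pipettable_ul / pool_vol)), call. = FALSE)
  }
  structure(list(pool_volume_ul = pool_vol,
                 diluent_volume_ul = final_volume_ul - pool_vol,
                 final_conc_pm = target_pM,
                 final_volume_ul = final_volume_ul),
            class = "dilution_plan")
}

#' @export
print.dilution_plan <- function(x, ...) {
  cat(sprintf("Pool:    %.3g µL\nDiluent: %.3g µL  (-> %g pM in %g µL)\n",
              x$pool_volume_ul, x$diluent_volume_ul, x$final_conc_pm,
              x$final_volume_ul))
  invisible(x)
}

#' @export
as.data.frame.dilution_plan <- function(x, ...) {
  data.frame(pool_volume_ul = x$pool_volume_ul,
             diluent_volume_ul = x$diluent_volume_ul,
             final_conc_pm = x$final_conc_pm,
             final_volume_ul = x$final_volume_ul)
}
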