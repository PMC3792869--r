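# Packaged reference measurements for EstGtA2 and its salt-bridge variants.

#' Reported stability measurements for EstGtA2 salt-bridge variants
#'
#' Published CD-derived melting temperatures (pH 8, and pH 10 for the
#' interloop His222Arg variant) for wild-type EstGtA2 and its combinatorial
#' alanine-shaving mutants of the five N'-exclusive salt bridges, together
#' with the reported extrapolated conformational stabilities at 25 C and
#' GuHCl denaturation midpoints where available. These values are used as
#' planted ground truth by the synthetic-curve generators and as the
#' reference for variant bookkeeping.
#'
#' Note: the published per-variant dTm column (\code{dtm_C_reported}) is not
#' always consistent with the difference of the published Tm values (e.g.
#' the K178A/R220A double mutant); this package always computes shifts from
#' fitted Tm values and carries the reported column for reference only.
#'
#' @return data frame with columns \code{variant}, \code{mutations},
#'   \code{ph}, \code{tm_C}, \code{tm_se}, \code{dtm_C_reported},
#'   \code{dg25_kcal_mol}, \code{guhcl_mid_M}.
#' @export
estgta2_variants <- function() {
  df <- data.frame(
    variant = c("WT", "M1a", "M1b", "M1c", "M1d", "M1e",
                "M2a", "M2b", "M2c", "M3a", "M3b", "M3c",
                "M4a", "M4b", "M4c", "WT_pH10", "H222R_pH10"),
    mutations = c("-", "R37A", "R54A", "R140A", "K178A", "R220A",
                  "R37A/R220A", "R140A/R220A", "K178A/R220A",
                  "R54A/R140A/R220A", "R54A/K178A/R220A", "R140A/K178A/R220A",
                  "R37A/R54A/R140A/R220A", "R37A/R140A/K178A/R220A",
                  "R54A/R140A/K178A/R220A", "-", "H222R"),
    ph = c(rep(8, 15), 10, 10),
    tm_C = c(64.2, 58.6, 55.6, 56.6, 55.3, 55.4,
             55.6, 54.1, 53.6, 53.9, 52.3, 50.4,
             53.2, 49.9, NA, 55.1, 57.6),
    tm_se = c(0.11, 0.31, 0.25, 0.23, 0.23, 0.15,
              0.18, 0.19, 0.29, 0.31, 0.17, 0.10,
              0.23, 0.30, NA, 0.21, 0.18),
    dtm_C_reported = c(NA, -5.6, -8.6, -7.6, -8.9, -8.8,
                       -8.6, -10.1, -13.6, -10.3, -11.9, -13.8,
                       -11.0, -14.3, NA, NA, 2.5),
    dg25_kcal_mol = c(11.8, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA,
                      4.9, NA, NA, NA, NA),
    guhcl_mid_M = c(2.2, NA, NA, NA, NA, NA, NA, NA, NA, NA, NA, 1.75,
                    NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
  df
}
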