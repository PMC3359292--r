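# Uncoupled Mooney-Rivlin material tables for the micro-scale regions.
# W = c1 (I1bar - 3) + c2 (I2bar - 3) + (K/2) (ln J)^2, coefficients in MPa.

#' Micro-scale material table
#'
#' Per-region coefficients of the uncoupled Mooney-Rivlin model. The defaults
#' are the study values: the ECM matches the macro-scale cartilage, and the
#' PCM and cell coefficients keep the stiffness ratios of the chondron
#' micromechanics literature they were scaled from.
#'
#' @param ecm,pcm,cell Length-3 numeric vectors `c(c1, c2, K)` in MPa.
#' @return A data.frame of class `material_table` with rows ECM, PCM, Cell
#'   and columns `c1`, `c2`, `K`.
#' @export
material_table <- function(ecm  = c(c1 = 1.6892, c2 = 0, K = 83.3333),
                           pcm  = c(c1 = 0.6838, c2 = 0, K = 1.0570),
                           cell = c(c1 = 0.0405, c2 = 0, K = 1.9980)) {
  tb <- rbind(ECM = ecm, PCM = pcm, Cell = cell)
  colnames(tb) <- c("c1", "c2", "K")
  if (any(tb[, "c1"] < 0)) stop("c1 must be >= 0")
  if (any(tb[, "K"] <= 0)) stop("bulk modulus K must be > 0")
  structure(as.data.frame(tb), class = c("material_table", "data.frame"))
}

#' Uniformly scale a material table
#'
#' Multiplies every coefficient (`c1`, `c2`, `K`) of every region by a common
#' factor, preserving all inter-region stiffness ratios — the protocol of the
#' material sensitivity study.
#'
#' @param table A [material_table()].
#' @param factor Positive scale factor.
#' @return A scaled `material_table`.
#' @export
scale_material_table <- function(table, factor) {
  stopifnot(inherits(table, "material_table"), factor > 0)
  out <- table
  out[, c("c1", "c2", "K")] <- out[, c("c1", "c2", "K")] * factor
  out
}

#' Reduce the PCM stiffness only
#'
#' Divides the PCM coefficients by `factor` (default 10), leaving ECM and
#' cell untouched — the stiffness-ratio-breaking case of the sensitivity
#' study.
#'
#' @param table A [material_table()].
#' @param factor Positive reduction factor.
#' @return A `material_table` with softened PCM.
#' @export
reduce_pcm_stiffness <- function(table, factor = 10) {
  stopifnot(inherits(table, "material_table"), factor > 0)
  out <- table
  out["PCM", c("c1", "c2", "K")] <- out["PCM", c("c1", "c2", "K")] / factor
  out
}
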