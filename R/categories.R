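#' BMI and fasting-glucose categories
#'
#' `classifyBmi` bins BMI, rounded to the nearest integer, into
#' normoweight (<= 25), overweight (26-29) and obese (>= 30) — the integer
#' reading of the published cut-offs, which leaves no gap between the
#' bands. `classifyFpg` bins fasting plasma glucose into normal
#' (< 100 mg/dL), prediabetic (100-120 mg/dL) and high (> 120 mg/dL).
#'
#' @param bmi,fpg numeric vectors (kg/m^2, mg/dL).
#' @return factor of category labels.
#' @export
classifyBmi <- function(bmi) {
  r <- round(bmi)
  factor(ifelse(r <= 25, "normoweight",
                ifelse(r <= 29, "overweight", "obese")),
         levels = c("normoweight", "overweight", "obese"))
}

#' @rdname classifyBmi
#' @export
classifyFpg <- function(fpg) {
  factor(ifelse(fpg < 100, "normal",
                ifelse(fpg <= 120, "prediabetic", "high")),
         levels = c("normal", "prediabetic", "high"))
}
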