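#' Estimated glomerular filtration rate (CKD-EPI 2021, race-free)
#'
#' Computes eGFR in mL/min/1.73 m^2 from serum creatinine, age and sex using
#' the 2021 CKD-EPI creatinine equation:
#' \deqn{142 \times \min(SCr/\kappa, 1)^{\alpha} \times \max(SCr/\kappa, 1)^{-1.200}
#'       \times 0.9938^{age} \times 1.012\,[\mathrm{if\ female}]}
#' with \eqn{\kappa = 0.7} (female) / 0.9 (male) and \eqn{\alpha = -0.241}
#' (female) / -0.302 (male).
#'
#' @param scr Serum creatinine in mg/dL (numeric vector, > 0).
#' @param age Age in years (>= 18).
#' @param sex Character vector, `"female"` or `"male"` (recycled).
#' @return Numeric vector of eGFR values (mL/min/1.73 m^2).
#' @examples
#' compute_egfr(0.8, 50, "female") # ~ 89.7
#' compute_egfr(1.0, 60, "male")   # ~ 86.2
#' @export
compute_egfr <- function(scr, age, sex) {
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(as.numeric(scr), n)
  age <- rep_len(as.numeric(age), n)
  sex <- rep_len(as.character(sex), n)
  if (any(!sex %in% c("female", "male"))) {
    stop("sex must be 'female' or 'male'", call. = FALSE)
  }
  if (any(!is.na(scr) & scr <= 0)) stop("scr must be > 0", call. = FALSE)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.241, -0.302)
  r <- scr / kappa
  142 * pmin(r, 1)^alpha * pmax(r, 1)^(-1.200) * 0.9938^age *
    ifelse(female, 1.012, 1)
}
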