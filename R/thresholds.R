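#' CDS diagnostic thresholds
#'
#' Cut-offs of the Chinese Diabetes Society (CDS) definition of metabolic
#' syndrome. A component is present when:
#' \describe{
#'   \item{overweight/obesity}{BMI >= `bmi` (kg/m^2)}
#'   \item{hypertension}{SBP >= `sbp` (mmHg) or DBP >= `dbp` (mmHg) or a
#'     prior hypertension diagnosis}
#'   \item{dyslipidemia}{fasting TG >= `tg` (mmol/L) or HDL < `hdl` (mmol/L)}
#'   \item{hyperglycemia}{FPG >= `fpg` (mmol/L) or 2-h post-meal glucose
#'     >= `pg2h` (mmol/L, when measured) or a prior hyperglycemia diagnosis}
#' }
#' Boundary semantics follow the printed inequalities exactly: `>=` for all
#' cuts except HDL, where the component is present strictly below the cut.
#'
#' @param bmi BMI cut, kg/m^2.
#' @param sbp Systolic blood-pressure cut, mmHg.
#' @param dbp Diastolic blood-pressure cut, mmHg.
#' @param tg Fasting triglyceride cut, mmol/L.
#' @param hdl HDL cholesterol cut, mmol/L (component present when HDL < cut).
#' @param fpg Fasting plasma-glucose cut, mmol/L.
#' @param pg2h 2-h post-meal glucose cut, mmol/L.
#' @return An object of class `cds_thresholds` (a named list of cuts).
#' @export
#' @examples
#' cds_thresholds()
#' cds_thresholds(bmi = 24) # a stricter overweight cut
cds_thresholds <- function(bmi = 25.0, sbp = 140, dbp = 90,
                           tg = 1.7, hdl = 0.9, fpg = 6.1, pg2h = 7.8) {
  cuts <- list(bmi = bmi, sbp = sbp, dbp = dbp, tg = tg, hdl = hdl,
               fpg = fpg, pg2h = pg2h)
  ok <- vapply(cuts, function(x) is.numeric(x) && length(x) == 1 && x > 0,
               logical(1))
  if (!all(ok)) {
    stop("all thresholds must be single positive numbers; offending: ",
         paste(names(cuts)[!ok], collapse = ", "))
  }
  structure(cuts, class = "cds_thresholds")
}

#' @export
print.cds_thresholds <- function(x, ...) {
  cat("CDS thresholds:\n")
  cat(sprintf("  BMI  >= %.1f kg/m^2\n", x$bmi))
  cat(sprintf("  SBP  >= %g mmHg | DBP >= %g mmHg | prior dx\n", x$sbp, x$dbp))
  cat(sprintf("  TG   >= %.1f mmol/L | HDL < %.1f mmol/L\n", x$tg, x$hdl))
  cat(sprintf("  FPG  >= %.1f mmol/L | 2h-PG >= %.1f mmol/L | prior dx\n",
              x$fpg, x$pg2h))
  invisible(x)
}
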