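#!/usr/bin/env Rscript
# Calibration of the inputs the published tables do not pin down:
#   * the level of background mortality (Gompertz q(age) = a*exp(b*(age-62)),
#     slope b fixed at 0.10 -- adult mortality doubling roughly every 7
#     years -- with the level a free),
#   * the LLIF short-term complication share of the decision tree
#     (PLIF starts all-well), and
#   * the arm-specific residual upfront index-surgery cost (ward, surgeon,
#     anesthesia and other components not itemised in the input table).
#
# Targets, in order: PLIF lifetime QALYs 13.63 and incremental
# effectiveness 0.15 QALY (hence LLIF 13.48) for (a, complication share);
# then total lifetime costs 30,124 / 33,003 USD fix the residuals exactly
# (cost is linear in the residual). Outputs are committed:
#   inst/extdata/mortality_calibrated.csv and the decision_tree / upfront
#   fields of inst/extdata/model_parameters.json, plus a calibration
# record in inst/extdata/calibration.json.
#
# Run from the repository root: Rscript analysis/01_calibrate.R

library(lumbarCUA)

cfg_path <- "inst/extdata/model_parameters.json"
mort_path <- "inst/extdata/mortality_calibrated.csv"

b <- 0.10
start_age <- 62; max_age <- 100
gompertz_table <- function(a) {
  ages <- start_age:max_age
  qx <- pmin(1, a * exp(b * (ages - start_age)))
  qx[ages >= max_age - 1] <- 1  # cohort extinct at max_age
  data.frame(age = ages, qx = qx)
}

# provisional table so the config loads; overwritten below
if (!file.exists(mort_path))
  write.csv(gompertz_table(0.005), mort_path, row.names = FALSE)
pset <- load_parameters(cfg_path)

with_calibration <- function(a, c_llif) {
  p <- pset
  p$mortality <- gompertz_table(a)
  p$tree$LLIF <- initial_allocation(list(complications = c_llif))
  p$upfront$LLIF$residual <- 0
  p$upfront$PLIF$residual <- 0
  p
}

objective <- function(par) {
  p <- with_calibration(exp(par[1]), plogis(par[2]))
  qP <- run_strategy(p, "PLIF")$qaly
  qL <- run_strategy(p, "LLIF")$qaly
  (qP - 13.63)^2 + ((qP - qL) - 0.15)^2
}

fit <- optim(c(log(0.005), qlogis(0.15)), objective,
             control = list(reltol = 1e-16, maxit = 10000))
a <- exp(fit$par[1]); c_llif <- plogis(fit$par[2])

p0 <- with_calibration(a, c_llif)
L <- run_strategy(p0, "LLIF"); P <- run_strategy(p0, "PLIF")
res_llif <- 30124 - L$cost
res_plif <- 33003 - P$cost
stopifnot(res_llif >= 0, res_plif >= 0)

cat(sprintf("Gompertz level a = %.10g (slope b = %.2f fixed)\n", a, b))
cat(sprintf("LLIF complication share = %.10g\n", c_llif))
cat(sprintf("residual upfront costs: LLIF %.4f, PLIF %.4f USD\n",
            res_llif, res_plif))
cat(sprintf("achieved QALYs: LLIF %.6f, PLIF %.6f (dE %.6f)\n",
            L$qaly, P$qaly, P$qaly - L$qaly))

# commit the calibrated mortality table and config fields
write.csv(gompertz_table(a), mort_path, row.names = FALSE)
cfg <- jsonlite::read_json(cfg_path)
cfg$decision_tree$LLIF$complications <- c_llif
cfg$upfront$LLIF$residual <- res_llif
cfg$upfront$PLIF$residual <- res_plif
jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, pretty = TRUE,
                     digits = NA)

jsonlite::write_json(list(
  method = paste("least squares on (PLIF QALYs - 13.63, incremental",
                 "effectiveness - 0.15); residuals close the cost",
                 "identity exactly"),
  gompertz = list(a = a, b = b),
  decision_tree_llif_complications = c_llif,
  residual_upfront = list(LLIF = res_llif, PLIF = res_plif),
  achieved = list(qaly_llif = L$qaly, qaly_plif = P$qaly,
                  cost_llif = 30124, cost_plif = 33003,
                  objective = fit$value)),
  "inst/extdata/calibration.json", auto_unbox = TRUE, pretty = TRUE,
  digits = NA)

# verify the committed configuration reproduces the base case
pfinal <- load_parameters(cfg_path)
bc <- run_base_case(pfinal)
print(bc$cea)
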