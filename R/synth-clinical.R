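#' Generate the synthetic clinical table
#'
#' Draws per-subject phenotypes for a case-control cohort. Binary flags
#' are Bernoulli at the configured prevalences. Severity scores follow a
#' linear model with planted effects:
#' `CARS = baseline(group) + diarrhea_beta * diarrhea + 2 s + e_c` and
#' `ABC = baseline(group) + insomnia_beta * insomnia + 8 s + e_a`, where
#' `s ~ N(0,1)` is a shared per-subject severity latent (inducing the
#' ABC~CARS correlation seen in real cohorts) and the idiosyncratic noise
#' scales (`sd 3.5` for CARS, `sd 13` for ABC) are chosen so the planted
#' effects are detectable at n = 51 with power >= 0.8. CARS is clipped to
#' `[15, 60]` and ABC to `[0, 158]` after noise addition.
#'
#' @param config a [synth_config()].
#' @return A `data.frame` (one row per subject): `subject`, `group`
#'   (`"ASD"`/`"TD"`), `subgroup` (`"ASD_D"`, `"ASD_noD"`, `"TD"`), `sex`,
#'   `age`, binary flags (`constipation`, `diarrhea`, `insomnia`,
#'   `hypersomnia`, `luts`, `repetitive` as 0/1), ordered covariates
#'   `income` and `father_edu`, and the `cars` and `abc` scores.
#' @export
gen_clinical <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 1L)
  nc <- config$n_cases; nt <- config$n_controls
  n <- nc + nt
  subject <- c(sprintf("A%03d", seq_len(nc)), sprintf("T%03d", seq_len(nt)))
  group <- rep(c("ASD", "TD"), c(nc, nt))

  flags <- c("male", "constipation", "diarrhea", "insomnia", "hypersomnia",
             "luts", "repetitive")
  draw <- function(prev, n) stats::rbinom(n, 1L, prev)
  fl <- sapply(flags, function(f) c(draw(config$prevalences$case[[f]], nc),
                                    draw(config$prevalences$control[[f]], nt)))
  fl <- as.data.frame(fl)

  age <- pmin(pmax(stats::rnorm(n, 5, 1.5), 2), 12)
  income <- sample(c("low", "middle", "high"), n, replace = TRUE,
                   prob = c(21, 25, 5) / 51)
  father_edu <- sample(c("junior_high", "senior_high", "junior_college",
                         "bachelor", "master"), n, replace = TRUE,
                       prob = c(18, 14, 15, 3, 1) / 51)

  severity <- stats::rnorm(n)
  cars_base <- ifelse(group == "ASD", 32, 17.5)
  cars <- cars_base + config$diarrhea_beta * fl$diarrhea +
    2 * severity + stats::rnorm(n, 0, 3.5)
  cars <- pmin(pmax(cars, 15), 60)
  abc_base <- ifelse(group == "ASD", 62, 15)
  abc <- abc_base + config$insomnia_beta * fl$insomnia +
    8 * severity + stats::rnorm(n, 0, 13)
  abc <- pmin(pmax(abc, 0), 158)

  subgroup <- ifelse(group == "TD", "TD",
                     ifelse(fl$diarrhea == 1, "ASD_D", "ASD_noD"))
  out <- data.frame(subject = subject, group = group, subgroup = subgroup,
                    sex = ifelse(fl$male == 1, "male", "female"), age = age,
                    income = factor(income, levels = c("low", "middle", "high")),
                    father_edu = factor(father_edu,
                                        levels = c("junior_high", "senior_high",
                                                   "junior_college", "bachelor",
                                                   "master")),
                    fl[, -1], cars = cars, abc = abc,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$subject
  out
}
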