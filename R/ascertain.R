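#' Ascertain a case-control sample from a simulated population
#'
#' Samples cases among individuals whose onset age lies at or below a current
#' age drawn from `case_age_dist`, and controls among individuals unaffected
#' at a current age drawn from `control_age_dist`. With `screened = TRUE`
#' controls are required never to onset within the model's age range
#' (emulating pathologically confirmed controls); otherwise controls only
#' need to be symptom-free at their current age, so some are latent cases
#' whose onset lies in their future. A `misdiagnosis_rate` replaces that
#' fraction of sampled cases with unaffected individuals while keeping the
#' case label, emulating clinically misdiagnosed patients.
#'
#' @param population A `cohort_table` from [simulate_liability_onset()].
#' @param n_cases,n_controls Requested sample sizes.
#' @param case_age_dist,control_age_dist Functions `n -> ages`.
#' @param screened Logical; confirmed disease-free controls when `TRUE`.
#' @param misdiagnosis_rate Fraction of case labels given to unaffected
#'   individuals (default 0).
#' @param seed Optional integer seed.
#' @return A `cohort_table` of `n_cases + n_controls` rows (cases first)
#'   with `age_years` set to the drawn assessment ages and `status` to the
#'   assigned label. Attributes: `latent_case_fraction` (sampled controls
#'   with a future onset), `misdiagnosed_ids`.
#' @export
ascertain <- function(population, n_cases, n_controls,
                      case_age_dist = function(n) stats::runif(n, 70, 90),
                      control_age_dist = function(n) stats::runif(n, 70, 90),
                      screened = TRUE, misdiagnosis_rate = 0, seed = NULL) {
  .assert(inherits(population, "data.frame") &&
            all(c("onset_age_years", "age_years") %in% names(population)),
          "'population' must be a cohort_table with onset ages")
  .assert(misdiagnosis_rate >= 0 && misdiagnosis_rate < 1,
          "'misdiagnosis_rate' must be in [0, 1)")
  onset <- population$onset_age_years
  .with_seed(seed, {
    ## cases: process drawn ages in increasing order, growing the pool of
    ## individuals whose onset is already reached; sample without replacement
    case_ages <- sort(case_age_dist(n_cases))
    ev <- which(!is.na(onset))
    ev <- ev[order(onset[ev])]
    pool <- integer(length(ev)); npool <- 0L; ptr <- 0L
    case_idx <- integer(n_cases)
    for (i in seq_len(n_cases)) {
      a <- case_ages[i]
      while (ptr < length(ev) && onset[ev[ptr + 1L]] <= a) {
        ptr <- ptr + 1L; npool <- npool + 1L; pool[npool] <- ev[ptr]
      }
      if (npool == 0L)
        stop(sprintf("cannot sample case %d: no unused individual with onset <= %.1f (stratum: cases)",
                     i, a), call. = FALSE)
      j <- if (npool == 1L) 1L else sample.int(npool, 1L)
      case_idx[i] <- pool[j]
      pool[j] <- pool[npool]; npool <- npool - 1L
    }

    ## controls: drawn ages in decreasing order so the pool of individuals
    ## with onset strictly after the current age only grows
    ctl_ages <- sort(control_age_dist(n_controls), decreasing = TRUE)
    never <- setdiff(which(is.na(onset)), case_idx)
    ctl_idx <- integer(n_controls)
    if (screened) {
      if (length(never) < n_controls)
        stop(sprintf("cannot sample %d screened controls: only %d individuals never onset (stratum: controls)",
                     n_controls, length(never)), call. = FALSE)
      ctl_idx <- sample(never, n_controls)
    } else {
      ev2 <- setdiff(which(!is.na(onset)), case_idx)
      ev2 <- ev2[order(onset[ev2], decreasing = TRUE)]
      pool2 <- c(sample(never), integer(length(ev2)))
      npool2 <- length(never); ptr2 <- 0L
      for (i in seq_len(n_controls)) {
        a <- ctl_ages[i]
        while (ptr2 < length(ev2) && onset[ev2[ptr2 + 1L]] > a) {
          ptr2 <- ptr2 + 1L; npool2 <- npool2 + 1L; pool2[npool2] <- ev2[ptr2]
        }
        if (npool2 == 0L)
          stop(sprintf("cannot sample control %d at age %.1f (stratum: controls)",
                       i, a), call. = FALSE)
        j <- if (npool2 == 1L) 1L else sample.int(npool2, 1L)
        ctl_idx[i] <- pool2[j]
        pool2[j] <- pool2[npool2]; npool2 <- npool2 - 1L
      }
    }

    ## misdiagnosis: swap a fraction of case slots for unaffected individuals
    n_mis <- round(misdiagnosis_rate * n_cases)
    mis_ids <- character(0)
    if (n_mis > 0) {
      slots <- sample.int(n_cases, n_mis)
      used <- c(case_idx, ctl_idx)
      for (s in slots) {
        a <- case_ages[s]
        cand <- which((is.na(onset) | onset > a) & !(seq_along(onset) %in% used))
        if (length(cand) == 0L)
          stop(sprintf("cannot draw misdiagnosed case at age %.1f (stratum: misdiagnosed cases)", a),
               call. = FALSE)
        pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
        case_idx[s] <- pick
        used <- c(used, pick)
      }
      mis_ids <- population$sample_id[case_idx[slots]]
    }

    idx <- c(case_idx, ctl_idx)
    out <- population[idx, , drop = FALSE]
    out$age_years <- c(case_ages, ctl_ages)
    out$status <- rep(c(1L, 0L), c(n_cases, n_controls))
    rownames(out) <- NULL
    latent <- !is.na(out$onset_age_years[out$status == 0L])
    structure(out, class = c("cohort_table", "data.frame"),
              latent_case_fraction = mean(latent),
              misdiagnosed_ids = mis_ids)
  })
}
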