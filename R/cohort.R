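#' Group-mean DCM parameter template for the inhibition circuit
#'
#' Encodes the qualitative connectivity structure of the right-lateralized
#' inhibition circuit as a group-mean generative model. Intrinsic couplings:
#' excitatory Cau->IFG, Cau->GP, GP->Thal and Thal->GP; inhibitory IFG->Cau
#' and IFG->Thal; a weak excitatory Thal->IFG; self log-scalings negative
#' for IFG, Cau and Thal and positive for GP. NoGo modulation carries
#' stronger inhibitory IFG->Cau, IFG->Thal and GP->Cau effects than Go, plus
#' negative self modulations of Cau and Thal; Go modulation includes an
#' excitatory GP->Cau and Thal->IFG. Driving input: NoGo excites all four
#' nodes, Go excites IFG only. Magnitudes are configuration values chosen so
#' that the noiseless model is stable under the default paradigm.
#'
#' @param scale Multiplier applied to all off-diagonal/driving magnitudes.
#' @return A [dcm_params()] object.
#' @export
default_truth_template <- function(scale = 1) {
  nodes <- dcm_nodes()
  A <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  A["IFG", "Cau"] <- 0.25    # Cau -> IFG +
  A["Cau", "IFG"] <- -0.25   # IFG -> Cau -
  A["GP", "Cau"] <- 0.20     # Cau -> GP +
  A["GP", "Thal"] <- 0.20    # Thal -> GP +
  A["Thal", "GP"] <- 0.20    # GP -> Thal +
  A["Thal", "IFG"] <- -0.25  # IFG -> Thal -
  A["IFG", "Thal"] <- 0.10   # Thal -> IFG, weak +
  A <- A * scale
  diag(A) <- c(-0.1, -0.1, 0.1, -0.1)

  Bn <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  Bn["Cau", "IFG"] <- -0.30
  Bn["Thal", "IFG"] <- -0.30
  Bn["Cau", "GP"] <- -0.30
  Bn <- Bn * scale
  diag(Bn) <- c(0, -0.15, 0, -0.15)

  Bg <- matrix(0, 4, 4, dimnames = list(nodes, nodes))
  Bg["Cau", "IFG"] <- -0.10
  Bg["Thal", "IFG"] <- -0.10
  Bg["Cau", "GP"] <- 0.20
  Bg["IFG", "Thal"] <- 0.15
  Bg <- Bg * scale
  diag(Bg) <- c(0.1, -0.1, 0, 0)

  C <- cbind(Go = c(0.1, 0, 0, 0), NoGo = c(0.15, 0.1, 0.1, 0.1)) * scale
  rownames(C) <- nodes
  dcm_params(A, list(Go = Bg, NoGo = Bn), C)
}

#' The six reported intrinsic connections of the circuit
#'
#' Names (in [param_names()] notation) and expected signs of the six
#' between-region intrinsic couplings that characterize the circuit:
#' Cau->IFG (+), IFG->Cau (-), Cau->GP (+), Thal->GP (+), GP->Thal (+),
#' IFG->Thal (-).
#'
#' @return Named numeric vector of signs.
#' @export
intrinsic_connection_signs <- function() {
  c("A[IFG,Cau]" = 1, "A[Cau,IFG]" = -1, "A[GP,Cau]" = 1,
    "A[GP,Thal]" = 1, "A[Thal,GP]" = 1, "A[Thal,IFG]" = -1)
}

#' Cohort specification for synthetic multi-subject data
#'
#' Describes a synthetic cohort: group-mean parameters, between-subject
#' variability, additive sex effects on named parameters, a performance
#' slope linking centered NoGo accuracy (%) to a named modulatory parameter,
#' behavioral accuracy/RT distributions, and the per-node signal-to-noise
#' ratio `SNR = sd(noiseless signal) / sd(noise)`.
#'
#' Default effects mirror the structure the pipeline is designed to detect:
#' females receive a more negative intrinsic Thal->GP coupling and a more
#' positive NoGo self-modulation of Thal (greater thalamic self-inhibition),
#' and NoGo accuracy is positively associated with the NoGo modulation of
#' Thal->IFG.
#'
#' @param n_subjects Number of subjects.
#' @param n_female Number of females (rest are male).
#' @param template Group-mean [dcm_params()].
#' @param subject_sd Between-subject SD added to every A/B/C parameter.
#' @param sex_effects Named vector of additive shifts applied to female
#'   subjects' parameters ([param_names()] notation).
#' @param performance_slope Named length-1 vector: change of the named
#'   parameter per percentage point of centered NoGo accuracy.
#' @param nogo_acc_mean,nogo_acc_sd,go_acc_mean,go_acc_sd Accuracy (%)
#'   distributions, truncated to `acc_bounds`.
#' @param acc_bounds Lower/upper truncation for accuracies.
#' @param rt_shift_ms,rt_meanlog,rt_sdlog Shifted-lognormal RT parameters;
#'   defaults give a mean correct-Go RT of about 314 ms.
#' @param snr Signal-to-noise ratio of the simulated BOLD.
#' @param age_mean,age_sd Age distribution (years).
#' @param seed Master seed; all subject-level randomness derives from it.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 20L, n_female = ceiling(n_subjects / 2),
                        template = default_truth_template(),
                        subject_sd = 0.05,
                        sex_effects = c("A[GP,Thal]" = -0.1,
                                        "B_NoGo[Thal,Thal]" = 0.1),
                        performance_slope = c("B_NoGo[IFG,Thal]" = 0.004),
                        nogo_acc_mean = 70.34, nogo_acc_sd = 15,
                        go_acc_mean = 98.47, go_acc_sd = 2,
                        acc_bounds = c(0, 100),
                        rt_shift_ms = 150, rt_meanlog = log(164.44) - 0.35^2 / 2,
                        rt_sdlog = 0.35,
                        snr = 1, age_mean = 21.6, age_sd = 2.3,
                        seed = 1L) {
  stopifnot(n_subjects >= 2, snr > 0, n_female <= n_subjects)
  nm <- param_names(template$nodes, names(template$B), colnames(template$C))
  bad <- setdiff(c(names(sex_effects), names(performance_slope)), nm)
  if (length(bad)) stop("unknown effect parameter(s): ", paste(bad, collapse = ", "))
  structure(as.list(environment())[setdiff(ls(), c("nm", "bad"))],
            class = "cohort_spec")
}

truncated_normal <- function(n, mean, sd, bounds) {
  x <- rnorm(n, mean, sd)
  for (i in seq_len(50)) {
    out <- x < bounds[1] | x > bounds[2]
    if (!any(out)) break
    x[out] <- rnorm(sum(out), mean, sd)
  }
  pmin(pmax(x, bounds[1]), bounds[2])
}

#' Generate a synthetic cohort of Go/NoGo subjects
#'
#' For each subject, true parameters are the template plus (i) the sex shift
#' for females, (ii) the performance slope times the subject's centered NoGo
#' accuracy, and (iii) iid Gaussian deviations with SD `subject_sd` on all
#' A/B/C entries. Each subject's BOLD is simulated noiselessly, the noise
#' precision is set from the requested SNR per node, and iid observation
#' noise is added. A draw whose simulation is unstable is rejected and
#' redrawn (at most 8 times, then the generator fails loudly). All
#' randomness derives from the master seed through per-subject substreams,
#' so cohorts are pure functions of `(cohort, paradigm)`.
#'
#' @param cohort A [cohort_spec()].
#' @param paradigm A [paradigm_spec()].
#' @param simulate If `FALSE`, skip BOLD simulation (truth and behavior
#'   only) -- useful when only group-level structure is needed.
#' @return List of class `cohort` whose elements are subject records (id,
#'   sex, age, accuracies, true parameters, `region_ts`, trial table), with
#'   the shared `design` and `trials` as attributes.
#' @export
generate_cohort <- function(cohort, paradigm = paradigm_spec(),
                            simulate = TRUE) {
  stopifnot(inherits(cohort, "cohort_spec"))
  par <- generate_paradigm(paradigm)
  design <- par$design
  sexes <- rep(c("female", "male"),
               c(cohort$n_female, cohort$n_subjects - cohort$n_female))
  theta0 <- pack_params(cohort$template)
  conn_idx <- c(param_block(names(theta0), "A"),
                param_block(names(theta0), "B"),
                param_block(names(theta0), "C"))

  subjects <- vector("list", cohort$n_subjects)
  for (i in seq_len(cohort$n_subjects)) {
    sub_seed <- (cohort$seed + 7919L * i) %% .Machine$integer.max
    rec <- with_seed(sub_seed, {
      age <- rnorm(1, cohort$age_mean, cohort$age_sd)
      nogo_acc <- truncated_normal(1, cohort$nogo_acc_mean,
                                   cohort$nogo_acc_sd, cohort$acc_bounds)
      go_acc <- truncated_normal(1, cohort$go_acc_mean, cohort$go_acc_sd,
                                 cohort$acc_bounds)
      ok <- FALSE
      for (try in 1:8) {
        theta <- theta0
        if (sexes[i] == "female") {
          theta[names(cohort$sex_effects)] <-
            theta[names(cohort$sex_effects)] + cohort$sex_effects
        }
        theta[names(cohort$performance_slope)] <-
          theta[names(cohort$performance_slope)] +
          cohort$performance_slope * (nogo_acc - cohort$nogo_acc_mean)
        theta[conn_idx] <- theta[conn_idx] +
          rnorm(length(conn_idx), 0, cohort$subject_sd)
        truth <- unpack_params(theta, cohort$template)
        if (!simulate) { ok <- TRUE; ts <- NULL; break }
        ts0 <- tryCatch(simulate_bold(truth, design), error = function(e) e)
        if (!inherits(ts0, "error")) {
          sd_sig <- apply(ts0$values, 2, sd)
          sd_noise <- pmax(sd_sig, 1e-3) / cohort$snr
          truth$noise_log_precision[] <- -2 * log(sd_noise)
          ts <- simulate_bold(truth, design,
                              noise_seed = (sub_seed + 13L) %% .Machine$integer.max)
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("subject ", i, ": no stable parameter draw in 8 attempts")
      behav <- generate_behavior(go_acc, nogo_acc, par$trials,
                                 rt_shift_ms = cohort$rt_shift_ms,
                                 rt_meanlog = cohort$rt_meanlog,
                                 rt_sdlog = cohort$rt_sdlog,
                                 seed = (sub_seed + 101L) %% .Machine$integer.max)
      list(id = sprintf("sub-%03d", i), sex = sexes[i], age = age,
           go_acc = go_acc, nogo_acc = nogo_acc, truth = truth,
           theta_true = theta, ts = ts, behavior = behav)
    })
    subjects[[i]] <- rec
  }
  structure(subjects, class = "cohort", design = design, trials = par$trials,
            spec = cohort)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic cohort:", length(x), "subjects (",
      sum(vapply(x, function(s) s$sex == "female", logical(1))), "female )\n")
  invisible(x)
}

#' Simulate trial-level Go/NoGo behavior
#'
#' Correctness is Bernoulli per trial at the subject's target accuracy for
#' the trial's condition. Responded trials (correct Go responses and
#' commission errors on NoGo trials) receive a shifted-lognormal reaction
#' time; correct NoGo trials and omission errors have no RT.
#'
#' @param go_acc,nogo_acc Target accuracies in percent.
#' @param trials Trial table from [generate_paradigm()].
#' @param rt_shift_ms,rt_meanlog,rt_sdlog Shifted-lognormal RT parameters.
#' @param seed RNG seed.
#' @return The trial table with added `response` ("press"/"withhold"),
#'   `correct` (logical) and `rt_ms` (NA when no response was made).
#' @export
generate_behavior <- function(go_acc, nogo_acc, trials,
                              rt_shift_ms = 150,
                              rt_meanlog = log(164.44) - 0.35^2 / 2,
                              rt_sdlog = 0.35, seed = 1L) {
  stopifnot(go_acc >= 0, go_acc <= 100, nogo_acc >= 0, nogo_acc <= 100)
  with_seed(seed, {
    p <- ifelse(trials$trial_type == "Go", go_acc, nogo_acc) / 100
    correct <- runif(nrow(trials)) < p
    responded <- (trials$trial_type == "Go" & correct) |
      (trials$trial_type == "NoGo" & !correct)
    rt <- rep(NA_real_, nrow(trials))
    rt[responded] <- rt_shift_ms +
      exp(rnorm(sum(responded), rt_meanlog, rt_sdlog))
    cbind(trials,
          response = ifelse(responded, "press", "withhold"),
          correct = correct, rt_ms = rt)
  })
}

#' @importFrom stats runif
NULL
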