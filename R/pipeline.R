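#' Run the full synthetic-study analysis pipeline
#'
#' Chains every stage of the workflow on synthetic data: generate a
#' dual-colour recording from ground-truth parameters, preprocess it to a
#' calcium/glutamate model pair, build feature normalisation from noisy
#' replicates, run sequential posterior inference, compute response indices,
#' fit the ridge baseline, and (optionally) run the time-resolved Sobol
#' analysis on the fitted posterior. Each stage draws its seed
#' deterministically from the manifest seed, so a rerun with the same config
#' reproduces the same outputs.
#'
#' @param study A \code{\link{synthetic_study}} (ground truth + observation
#'   model).
#' @param seed Master seed.
#' @param rounds,n_sims Inference budget; defaults 3 and 3000.
#' @param epochs MDN epochs per round; default 800.
#' @param n_norm_replicates Noisy replicates used for feature normalisation;
#'   default 20.
#' @param sobol_n Base samples for the Sobol stage; 0 skips it.
#' @param verbose Print stage progress.
#' @return List with \code{manifest}, \code{recording}, \code{pair},
#'   \code{target_features}, \code{normalisation}, \code{inference},
#'   \code{predictive}, \code{indices}, \code{ridge} (fit, prediction and
#'   its relevant loss) and \code{sobol}.
#' @export
run_pipeline <- function(study, seed = 1, rounds = 3, n_sims = 3000,
                         epochs = 800, n_norm_replicates = 20, sobol_n = 0,
                         verbose = FALSE) {
  stopifnot(inherits(study, "synthetic_study"))
  stage_seed <- function(k) as.integer((abs(seed) * 31L + k) %% 2147483647L)
  manifest <- list(seed = seed,
                   stage_seeds = vapply(1:6, stage_seed, integer(1)),
                   study = unclass(study)[setdiff(names(unclass(study)),
                                                  "params")],
                   params = unclass(study$params),
                   rounds = rounds, n_sims = n_sims, epochs = epochs,
                   version = as.character(utils::packageVersion("ribbonsyn")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (verbose) message("stage 1: synthetic recording")
  rec <- generate_recording(study, seed = stage_seed(1))
  if (verbose) message("stage 2: preprocessing")
  pair <- preprocess_recording(rec$observed$calcium_f,
                               rec$observed$glutamate_f, rec$annotations,
                               model_dt = study$dt)
  if (verbose) message("stage 3: features and normalisation")
  reps <- lapply(seq_len(n_norm_replicates), function(r) {
    rr <- generate_recording(study, seed = stage_seed(2) + r)
    pr <- preprocess_recording(rr$observed$calcium_f,
                               rr$observed$glutamate_f, rr$annotations,
                               model_dt = study$dt)
    extract_features(pr$glutamate, rr$annotations)
  })
  normalisation <- feature_normalisation(do.call(rbind, reps))
  target_features <- extract_features(pair$glutamate, rec$annotations)
  if (verbose) message("stage 4: sequential inference")
  inf <- run_sequential_inference(target_features, normalisation,
                                  pair$calcium, rec$annotations,
                                  rounds = rounds, n_sims = n_sims,
                                  epochs = epochs, seed = stage_seed(3),
                                  verbose = verbose)
  pred <- posterior_predictive(inf$final, pair$calcium, rec$annotations,
                               seed = stage_seed(4))
  if (verbose) message("stage 5: response indices and ridge baseline")
  mst <- max_sustain_transience(pair$glutamate, rec$annotations$dark_onsets)
  ridge <- fit_ridge_baseline(pair$calcium, pair$glutamate)
  ridge_pred <- predict_ridge(ridge, pair$calcium)
  ridge_loss <- relevant_loss(extract_features(ridge_pred, rec$annotations),
                              target_features, normalisation)$R
  sobol <- NULL
  if (sobol_n > 0) {
    if (verbose) message("stage 6: sensitivity analysis")
    draws <- posterior_samples(inf$final, 2000, seed = stage_seed(5))
    sobol <- sobol_release(draws$natural, pair$calcium, n = sobol_n,
                           seed = stage_seed(6))
  }
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  list(manifest = manifest, recording = rec, pair = pair,
       target_features = target_features, normalisation = normalisation,
       inference = inf, predictive = pred, indices = mst,
       ridge = list(fit = ridge, prediction = ridge_pred,
                    relevant_loss = ridge_loss),
       sobol = sobol)
}
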