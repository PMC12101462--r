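#' Linear pair-basis surrogate potential
#'
#' A trainable potential that is linear in its parameters: the energy is
#' a fixed radial basis on pair distances, by default the
#' cutoff-shifted inverse powers r^-12 and r^-6 (so any truncated,
#' shifted Lennard-Jones with the same cutoff lies exactly in the span),
#' with coefficients obtained by regularised least squares on energies,
#' forces and virials.  It plays the role a fine-tunable
#' machine-learned potential plays in production workflows while
#' remaining exactly fittable at desk scale.
#'
#' @param powers inverse powers of the radial basis.
#' @param cutoff truncation radius (Angstrom); each basis function is
#'   shifted to zero at the cutoff.
#' @param coef starting coefficients (kJ/mol A^power), default all 0.
#' @param skin pair-list margin.
#' @return potential of class `pair_basis_surrogate`.
#' @export
surrogate_pair_potential <- function(powers = c(12, 6), cutoff = 9,
                                     coef = numeric(length(powers)),
                                     skin = 0.6) {
  stopifnot(length(coef) == length(powers))
  structure(list(powers = powers, cutoff = cutoff, coef = coef,
                 skin = skin, name = "pair_basis_surrogate"),
            class = c("pair_basis_surrogate", "potential"))
}

# per-structure basis features: energy (K), forces (3N x K), virial (9 x K)
surrogate_features <- function(potential, config) {
  pl <- pair_list(config, potential$cutoff)
  pv <- pair_vectors(pl, config$positions)
  r2 <- rowSums(pv^2)
  keep <- r2 < potential$cutoff^2
  pl <- list(i = pl$i[keep], j = pl$j[keep],
             shift = pl$shift[keep, , drop = FALSE])
  pv <- pv[keep, , drop = FALSE]
  r <- sqrt(r2[keep])
  K <- length(potential$powers)
  n <- n_atoms(config)
  eK <- numeric(K)
  fK <- matrix(0, 3 * n, K)
  vK <- matrix(0, 9, K)
  for (k in seq_len(K)) {
    p <- potential$powers[k]
    eK[k] <- sum(r^-p - potential$cutoff^-p)
    dphi_over_r <- -p * r^(-p - 2)       # (d/dr r^-p) / r
    fpair <- dphi_over_r * pv            # force-basis on atom i
    fK[, k] <- as.vector(t(accumulate_pair_forces(n, pl, fpair)))
    vK[, k] <- as.vector(-crossprod(pv, fpair))
  }
  list(energy = eK, forces = fK, virial = vK)
}

#' @export
evaluate.pair_basis_surrogate <- function(potential, config, cache = NULL) {
  feat <- surrogate_features(potential, config)
  list(energy = sum(feat$energy * potential$coef),
       forces = matrix(feat$forces %*% potential$coef, ncol = 3,
                       byrow = TRUE),
       virial = if (config$pbc)
         matrix(feat$virial %*% potential$coef, 3, 3) else NULL,
       cache = cache)
}

#' Label structures with a reference potential
#'
#' @param configs list of [atoms] objects (or a selection from the
#'   sampler carrying `configs` and `provenance`).
#' @param reference_potential potential used for the labels.
#' @return a `training_set`: configs plus energies, forces, virials and
#'   provenance.
#' @export
label_structures <- function(configs, reference_potential) {
  prov <- NULL
  if (!is.null(configs$configs)) {
    prov <- configs$provenance
    configs <- configs$configs
  }
  if (length(configs) == 0) stop("empty structure set")
  labels <- lapply(configs, function(cfg)
    evaluate(reference_potential, cfg)[c("energy", "forces", "virial")])
  structure(list(configs = configs, labels = labels, provenance = prov,
                 label_potential =
                   reference_potential$name %||% "reference"),
            class = "training_set")
}

#' Fit a linear surrogate to a labelled training set
#'
#' Regularised (ridge) least squares on energies, forces and virials
#' with relative weights 1 : 0.1 : 0.1; a held-out validation split
#' reports energy, force and stress RMSEs.  Deterministic for a fixed
#' seed.
#'
#' @param surrogate a [surrogate_pair_potential].
#' @param training_set a `training_set` from [label_structures].
#' @param weights length-3 weights for energy, force, virial rows.
#' @param ridge Tikhonov regularisation.
#' @param validation_frac held-out fraction (>= 1 structure when > 0).
#' @param seed RNG seed for the split.
#' @return list: `potential` (fitted), `report` (train/validation RMSEs
#'   and training-set size), `coef`.
#' @export
fit_surrogate <- function(surrogate, training_set,
                          weights = c(1, 0.1, 0.1), ridge = 1e-10,
                          validation_frac = 0.1, seed = 1) {
  if (!inherits(training_set, "training_set")) stop("need a training_set")
  ns <- length(training_set$configs)
  if (ns == 0) stop("empty training set")
  set.seed(seed)
  nval <- if (validation_frac > 0 && ns >= 5)
    max(1L, floor(validation_frac * ns)) else 0L
  val_idx <- if (nval > 0) sort(sample.int(ns, nval)) else integer(0)
  tr_idx <- setdiff(seq_len(ns), val_idx)
  feats <- lapply(training_set$configs,
                  function(cfg) surrogate_features(surrogate, cfg))
  rows_for <- function(idx) {
    A <- list(); b <- list()
    for (i in idx) {
      f <- feats[[i]]; lab <- training_set$labels[[i]]
      A[[length(A) + 1]] <- weights[1] * rbind(f$energy)
      b[[length(b) + 1]] <- weights[1] * lab$energy
      A[[length(A) + 1]] <- weights[2] * f$forces
      b[[length(b) + 1]] <- weights[2] * as.vector(t(lab$forces))
      if (!is.null(lab$virial)) {
        A[[length(A) + 1]] <- weights[3] * f$virial
        b[[length(b) + 1]] <- weights[3] * as.vector(lab$virial)
      }
    }
    list(A = do.call(rbind, A), b = unlist(b))
  }
  tr <- rows_for(tr_idx)
  AtA <- crossprod(tr$A)
  # per-column relative Tikhonov: basis functions differ by orders of
  # magnitude in scale, so a single absolute ridge would distort the
  # small-scale columns
  AtA <- AtA + diag(ridge * pmax(diag(AtA), 1e-300), ncol(AtA))
  cond <- kappa(AtA)
  coef <- tryCatch(solve(AtA, crossprod(tr$A, tr$b)),
                   error = function(e)
                     stop("singular surrogate fit (condition number ",
                          format(cond), "): ", conditionMessage(e)))
  fitted <- surrogate
  fitted$coef <- as.numeric(coef)
  rmse_on <- function(idx) {
    if (length(idx) == 0) return(c(energy = NA, force = NA, stress = NA))
    de <- df <- dv <- numeric(0)
    for (i in idx) {
      f <- feats[[i]]; lab <- training_set$labels[[i]]
      cfg <- training_set$configs[[i]]
      nm <- cfg$info$n_molecules %||% 1
      de <- c(de, (sum(f$energy * fitted$coef) - lab$energy) / nm)
      df <- c(df, f$forces %*% fitted$coef - as.vector(t(lab$forces)))
      if (!is.null(lab$virial))
        dv <- c(dv, (f$virial %*% fitted$coef - as.vector(lab$virial)) /
                  det(cfg$cell))
    }
    c(energy = sqrt(mean(de^2)), force = sqrt(mean(df^2)),
      stress = if (length(dv)) sqrt(mean(dv^2)) else NA)
  }
  list(potential = fitted, coef = fitted$coef,
       report = list(n_train = length(tr_idx), n_validation = nval,
                     train_rmse = rmse_on(tr_idx),
                     validation_rmse = rmse_on(val_idx),
                     condition_number = cond))
}
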