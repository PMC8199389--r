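#' Emotion labels used throughout the package
#'
#' The four emotional states, in the fixed integer-encoding order used by
#' the classifier: neutral = 0, happy = 1, excited = 2, angry = 3.
#'
#' @return Character vector of the four labels.
#' @export
emotion_levels <- function() c("neutral", "happy", "excited", "angry")

#' Features carried by the per-class statistical model
#' @return Character vector of the seven modeled features.
#' @export
emotion_features_modeled <- function() {
  c("age", "bmi", "bvp", "gsr", "skt", "valence", "arousal")
}

# Per-class means/SDs and pairwise Pearson correlations of the study
# population (1200 employees across 10 organizations).  Means/SDs are over
# (age [y], bmi [kg/m^2], bvp, gsr [sensor units], skt [deg C],
#  valence, arousal [1-10 affect scores]).
.class_params <- local({
  feat <- c("age", "bmi", "bvp", "gsr", "skt", "valence", "arousal")

  mk_corr <- function(lower) {
    R <- diag(7)
    dimnames(R) <- list(feat, feat)
    for (p in lower) {
      R[p[[1]], p[[2]]] <- p[[3]]
      R[p[[2]], p[[1]]] <- p[[3]]
    }
    R
  }

  list(
    neutral = list(
      n = 320L,
      mean = c(age = 47.40, bmi = 22.75, bvp = 36.19, gsr = 4.95,
               skt = 29.02, valence = 5.38, arousal = 5.29),
      sd   = c(age = 10.47, bmi = 3.68, bvp = 0.61, gsr = 0.07,
               skt = 0.01, valence = 0.72, arousal = 0.44),
      corr = mk_corr(list(
        list("bmi", "age", 0.24),  list("bmi", "arousal", 0.01),
        list("bmi", "valence", -0.13), list("bmi", "skt", 0.09),
        list("bmi", "gsr", 0.10),  list("bmi", "bvp", -0.08),
        list("bvp", "age", -0.14), list("bvp", "arousal", -0.005),
        list("bvp", "valence", -0.006), list("bvp", "skt", -0.14),
        list("bvp", "gsr", -0.14),
        list("gsr", "age", 0.04),  list("gsr", "arousal", 0.09),
        list("gsr", "valence", 0.16), list("gsr", "skt", 0.94),
        list("skt", "age", 0.04),  list("skt", "arousal", 0.11),
        list("skt", "valence", 0.19),
        list("valence", "age", -0.11), list("valence", "arousal", 0.02),
        list("arousal", "age", -0.01)))
    ),
    happy = list(
      n = 349L,
      mean = c(age = 46.26, bmi = 22.94, bvp = 35.30, gsr = 6.19,
               skt = 29.08, valence = 7.28, arousal = 5.74),
      sd   = c(age = 11.50, bmi = 4.27, bvp = 0.69, gsr = 0.05,
               skt = 0.20, valence = 0.60, arousal = 0.41),
      corr = mk_corr(list(
        list("bmi", "age", 0.28),  list("bmi", "arousal", 0.04),
        list("bmi", "valence", -0.04), list("bmi", "skt", -0.06),
        list("bmi", "gsr", 0.06),  list("bmi", "bvp", 0.01),
        list("bvp", "age", 0.06),  list("bvp", "arousal", -0.17),
        list("bvp", "valence", 0.16), list("bvp", "skt", 0.03),
        list("bvp", "gsr", 0.03),
        list("gsr", "age", 0.01),  list("gsr", "arousal", 0.09),
        list("gsr", "valence", 0.16), list("gsr", "skt", -0.19),
        list("skt", "age", 0.03),  list("skt", "arousal", -0.08),
        list("skt", "valence", -0.42),
        list("valence", "age", -0.06), list("valence", "arousal", 0.62),
        list("arousal", "age", -0.04)))
    ),
    excited = list(
      n = 295L,
      mean = c(age = 41.88, bmi = 22.64, bvp = 35.88, gsr = 8.15,
               skt = 28.69, valence = 9.28, arousal = 6.71),
      sd   = c(age = 7.84, bmi = 3.14, bvp = 0.42, gsr = 0.70,
               skt = 0.01, valence = 0.23, arousal = 0.45),
      corr = mk_corr(list(
        list("bmi", "age", 0.19),  list("bmi", "arousal", 0.13),
        list("bmi", "valence", 0.05), list("bmi", "skt", 0.06),
        list("bmi", "gsr", 0.02),  list("bmi", "bvp", -0.08),
        list("bvp", "age", 0.01),  list("bvp", "arousal", -0.30),
        list("bvp", "valence", -0.10), list("bvp", "skt", 0.18),
        list("bvp", "gsr", 0.02),
        list("gsr", "age", -0.04), list("gsr", "arousal", 0.08),
        list("gsr", "valence", 0.06), list("gsr", "skt", 0.01),
        list("skt", "age", -0.03), list("skt", "arousal", -0.36),
        list("skt", "valence", -0.03),
        list("valence", "age", 0.01), list("valence", "arousal", 0.35),
        list("arousal", "age", 0.15)))
    ),
    angry = list(
      n = 236L,
      mean = c(age = 39.72, bmi = 22.50, bvp = 34.81, gsr = 5.67,
               skt = 29.14, valence = 2.45, arousal = 7.41),
      sd   = c(age = 14.38, bmi = 3.50, bvp = 1.43, gsr = 0.67,
               skt = 0.18, valence = 0.82, arousal = 0.85),
      corr = mk_corr(list(
        list("bmi", "age", 0.49),  list("bmi", "arousal", -0.09),
        list("bmi", "valence", 0.09), list("bmi", "skt", 0.12),
        list("bmi", "gsr", 0.03),  list("bmi", "bvp", -0.12),
        list("bvp", "age", -0.08), list("bvp", "arousal", 0.08),
        list("bvp", "valence", -0.14), list("bvp", "skt", -0.23),
        list("bvp", "gsr", 0.07),
        list("gsr", "age", -0.05), list("gsr", "arousal", -0.05),
        list("gsr", "valence", -0.06), list("gsr", "skt", 0.34),
        list("skt", "age", 0.13),  list("skt", "arousal", -0.49),
        list("skt", "valence", 0.10),
        list("valence", "age", 0.14), list("valence", "arousal", -0.53),
        list("arousal", "age", -0.09)))
    )
  )
})

#' Per-class statistical model of the study population
#'
#' Returns, for each of the four emotional states, the mean vector,
#' standard-deviation vector, pairwise Pearson correlation matrix and class
#' proportion that parameterize the synthetic data generator.  The
#' correlation matrix in each class is additionally projected to the
#' nearest positive-semidefinite correlation matrix (`corr_psd`) so that it
#' can serve as a valid joint correlation matrix; for these parameters the
#' printed matrices are already positive-definite and the projection is a
#' no-op.
#'
#' @return Named list (one element per emotion, in encoding order) with
#'   components `emotion`, `n`, `proportion`, `mean`, `sd`, `corr`,
#'   `corr_psd`.
#' @examples
#' st <- emotion_class_stats()
#' st$excited$mean[["gsr"]]    # 8.15
#' st$angry$corr["valence", "arousal"]  # -0.53
#' @export
emotion_class_stats <- function() {
  n_total <- sum(vapply(.class_params, `[[`, integer(1), "n"))
  out <- lapply(names(.class_params), function(em) {
    p <- .class_params[[em]]
    stopifnot(all(p$sd > 0), all(abs(p$corr) <= 1),
              isSymmetric(p$corr), all(diag(p$corr) == 1))
    list(emotion = em,
         n = p$n,
         proportion = p$n / n_total,
         mean = p$mean,
         sd = p$sd,
         corr = p$corr,
         corr_psd = nearest_psd(p$corr))
  })
  names(out) <- names(.class_params)
  out
}

#' Nearest positive-semidefinite correlation matrix
#'
#' Projects a symmetric matrix with unit diagonal onto the set of valid
#' correlation matrices by alternating eigenvalue clipping (negative
#' eigenvalues set to zero) with restoration of the unit diagonal, in the
#' spirit of Higham's alternating-projections method.  A matrix that is
#' already positive-semidefinite is returned unchanged.
#'
#' @param corr Symmetric numeric matrix with unit diagonal.
#' @param tol Eigenvalue tolerance; the result is guaranteed to have
#'   minimum eigenvalue `>= -tol`.
#' @param max_iter Maximum number of alternating projections.
#' @return Symmetric positive-semidefinite matrix with unit diagonal.
#' @export
nearest_psd <- function(corr, tol = 1e-10, max_iter = 100) {
  if (!is.matrix(corr) || !isSymmetric(unname(corr), tol = 1e-8))
    stop("`corr` must be a symmetric matrix")
  dn <- dimnames(corr)
  X <- unname((corr + t(corr)) / 2)
  for (i in seq_len(max_iter)) {
    e <- eigen(X, symmetric = TRUE)
    if (min(e$values) >= -tol && max(abs(diag(X) - 1)) < 1e-12) break
    X <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
    X <- (X + t(X)) / 2
    # renormalize to unit diagonal (guard against zero diagonal entries)
    d <- pmax(diag(X), .Machine$double.eps)
    X <- X / sqrt(outer(d, d))
    diag(X) <- 1
  }
  dimnames(X) <- dn
  X
}
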