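#' @importFrom MASS mvrnorm
#' @importFrom stats rnorm runif rbinom
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is untouched.  seed = NULL runs under the current RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed))
    stop("`seed` must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}

# Deterministic fan-out of a master seed into per-stage seeds (kept below
# 2^31 so they remain valid R integer seeds).
derive_seed <- function(seed, index) {
  (as.double(seed) * 48271 + 7919 * as.double(index)) %% 2147483647
}

default_clip_ranges <- function() {
  list(age = c(0, 100), bmi = c(10, 60), bvp = c(0, Inf), gsr = c(0, Inf),
       skt = c(20, 40), valence = c(0, 10), arousal = c(0, 10))
}

#' Configuration for the synthetic employee-emotion generator
#'
#' Defaults reproduce the study population: 1200 base records across 10
#' organizations with the printed rank distribution, 52.2% male, augmented
#' to 5000 records by jittered resampling.
#'
#' @param n_base Number of base records (default 1200).
#' @param n_augmented Target size after augmentation (default 5000).
#' @param male_fraction Probability that a sampled employee is male.
#' @param rank_counts Integer 10-vector of employees per organizational
#'   rank 1..10; must sum to `n_base`.
#' @param seed Integer seed for all sampling.
#' @param clip_ranges Named list of `c(lo, hi)` plausibility bounds applied
#'   to sampled features (clipping; see the methods vignette for how the
#'   defaults were chosen so they essentially never bind).
#' @param augment_noise_scale Jitter SD as a fraction of the per-class
#'   feature SD used during augmentation (default 0.05).
#' @return Object of class `emotion_sim_config`.
#' @export
emotion_sim_config <- function(n_base = 1200L,
                               n_augmented = 5000L,
                               male_fraction = 0.522,
                               rank_counts = c(130L, 131L, 121L, 127L, 123L,
                                               135L, 100L, 125L, 110L, 98L),
                               seed = 1L,
                               clip_ranges = default_clip_ranges(),
                               augment_noise_scale = 0.05) {
  n_base <- as.integer(n_base)
  n_augmented <- as.integer(n_augmented)
  if (n_augmented < n_base) stop("`n_augmented` must be >= `n_base`")
  if (length(rank_counts) != 10L)
    stop("`rank_counts` must have 10 entries (ranks 1..10)")
  if (n_base != 1200L && identical(rank_counts,
                                   c(130L, 131L, 121L, 127L, 123L,
                                     135L, 100L, 125L, 110L, 98L))) {
    # rescale the default rank distribution to the requested size
    rank_counts <- largest_remainder(rank_counts / 1200, n_base)
  }
  if (sum(rank_counts) != n_base)
    stop("`rank_counts` must sum to `n_base`")
  structure(list(n_base = n_base, n_augmented = n_augmented,
                 male_fraction = male_fraction,
                 rank_counts = as.integer(rank_counts),
                 seed = seed, clip_ranges = clip_ranges,
                 augment_noise_scale = augment_noise_scale),
            class = "emotion_sim_config")
}

# Allocate `total` counts to classes with probabilities `prop` by the
# largest-remainder rule (deterministic; reproduces printed class counts).
largest_remainder <- function(prop, total) {
  exact <- prop / sum(prop) * total
  base <- floor(exact)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

clip_features <- function(df, clip_ranges) {
  for (f in names(clip_ranges)) {
    if (f %in% names(df)) {
      r <- clip_ranges[[f]]
      df[[f]] <- pmin(pmax(df[[f]], r[1]), r[2])
    }
  }
  df
}

#' Sample synthetic records of one emotional state
#'
#' Draws from the class-conditional multivariate Gaussian defined by the
#' class mean/SD vectors and the (PSD-projected) correlation matrix over
#' (age, bmi, bvp, gsr, skt, valence, arousal).  Gender is Bernoulli,
#' height is Gaussian (170 cm, SD 10), weight is back-derived from the
#' sampled BMI, and organizational rank follows the study rank
#' distribution.  Features are clipped to the configured plausibility
#' ranges after sampling.
#'
#' @param emotion One of `emotion_levels()`.
#' @param n Number of records (>= 0).
#' @param seed Optional seed; identical seeds give identical output.
#' @param stats Per-class parameterization, as from [emotion_class_stats()].
#' @param config An [emotion_sim_config()].
#' @return Data frame of employee records (one row each).
#' @export
sample_emotion_class <- function(emotion, n, seed = NULL,
                                 stats = emotion_class_stats(),
                                 config = emotion_sim_config()) {
  if (!emotion %in% emotion_levels())
    stop("unknown emotion label: ", emotion)
  n <- as.integer(n)
  if (n < 0) stop("`n` must be >= 0")
  cols <- c("subject_id", "org_rank", "gender", "age", "height", "weight",
            "bmi", "bvp", "gsr", "skt", "valence", "arousal", "emotion")
  if (n == 0) {
    out <- data.frame(subject_id = character(), org_rank = integer(),
                      gender = character(), age = double(),
                      height = double(), weight = double(), bmi = double(),
                      bvp = double(), gsr = double(), skt = double(),
                      valence = double(), arousal = double(),
                      emotion = character(), stringsAsFactors = FALSE)
    return(out[cols])
  }
  st <- stats[[emotion]]
  with_seed(seed, {
    Sigma <- (st$sd %o% st$sd) * st$corr_psd
    X <- MASS::mvrnorm(n, mu = st$mean, Sigma = Sigma)
    X <- matrix(X, nrow = n, dimnames = list(NULL, names(st$mean)))
    gender <- ifelse(stats::rbinom(n, 1, config$male_fraction) == 1,
                     "male", "female")
    height <- pmin(pmax(stats::rnorm(n, 170, 10), 140), 210)
    org_rank <- sample(rep.int(1:10, times = config$rank_counts), n,
                       replace = TRUE)
    df <- data.frame(
      subject_id = sprintf("S%06d", seq_len(n)),
      org_rank = as.integer(org_rank),
      gender = gender,
      age = X[, "age"], height = height,
      weight = NA_real_, bmi = X[, "bmi"],
      bvp = X[, "bvp"], gsr = X[, "gsr"], skt = X[, "skt"],
      valence = X[, "valence"], arousal = X[, "arousal"],
      emotion = emotion, stringsAsFactors = FALSE)
    df <- clip_features(df, config$clip_ranges)
    df$weight <- df$bmi * (df$height / 100)^2
    df[cols]
  })
}

#' Generate the full synthetic study dataset
#'
#' Produces exactly `n_base` employee records whose class counts follow
#' the study proportions via deterministic largest-remainder allocation
#' (236 angry, 349 happy, 295 excited, 320 neutral at n = 1200), with the
#' printed organizational-rank distribution and unique subject IDs.
#'
#' @param config An [emotion_sim_config()].
#' @return Data frame of `n_base` records.
#' @examples
#' d <- simulate_employees(emotion_sim_config(seed = 7))
#' table(d$emotion)
#' @export
simulate_employees <- function(config = emotion_sim_config()) {
  stopifnot(inherits(config, "emotion_sim_config"))
  stats <- emotion_class_stats()
  props <- vapply(stats, `[[`, double(1), "proportion")
  counts <- largest_remainder(props, config$n_base)
  names(counts) <- names(stats)
  parts <- lapply(seq_along(counts), function(i) {
    em <- names(counts)[i]
    sample_emotion_class(em, counts[i],
                         seed = derive_seed(config$seed, i),
                         stats = stats, config = config)
  })
  df <- do.call(rbind, parts)
  with_seed(derive_seed(config$seed, 101), {
    # ranks follow the printed distribution exactly; assignment to
    # employees (hence to emotions) is a seeded permutation
    ranks <- rep.int(1:10, times = config$rank_counts)
    df$org_rank <- as.integer(sample(ranks, config$n_base))
  })
  df$subject_id <- sprintf("S%06d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df
}

#' Augment a dataset by jittered resampling
#'
#' Adds records until `target_n` is reached.  Added records are resampled
#' (with replacement, per class) from the input and jittered with Gaussian
#' noise of SD `noise_scale` times the per-class empirical feature SD;
#' labels, gender and rank are inherited from the source record and weight
#' is re-derived from the jittered BMI.  The number of added records per
#' class is allocated by largest remainder so class proportions are
#' preserved to within one record.
#'
#' @param records Data frame of employee records.
#' @param target_n Desired total size (>= `nrow(records)`).
#' @param noise_scale Jitter SD as a fraction of the per-class feature SD;
#'   0 duplicates records exactly.
#' @param seed Optional seed.
#' @param clip_ranges Plausibility bounds applied after jittering.
#' @return Data frame with `target_n` rows (originals first).
#' @export
augment_records <- function(records, target_n, noise_scale = 0.05,
                            seed = NULL,
                            clip_ranges = default_clip_ranges()) {
  target_n <- as.integer(target_n)
  if (nrow(records) == 0 && target_n > 0)
    stop("cannot augment an empty dataset")
  if (target_n < nrow(records))
    stop("`target_n` must be >= nrow(records)")
  n_add_total <- target_n - nrow(records)
  if (n_add_total == 0) return(records)
  feat <- emotion_features_modeled()
  cls_counts <- table(factor(records$emotion, levels = emotion_levels()))
  present <- names(cls_counts)[cls_counts > 0]
  n_add <- largest_remainder(as.numeric(cls_counts[present]), n_add_total)
  names(n_add) <- present
  with_seed(seed, {
    added <- lapply(present, function(em) {
      m <- n_add[[em]]
      if (m == 0) return(NULL)
      sub <- records[records$emotion == em, , drop = FALSE]
      sds <- vapply(feat, function(f) stats::sd(sub[[f]]), double(1))
      sds[!is.finite(sds)] <- 0
      pick <- sub[sample(nrow(sub), m, replace = TRUE), , drop = FALSE]
      if (noise_scale > 0) {
        for (f in feat)
          pick[[f]] <- pick[[f]] +
            stats::rnorm(m, 0, noise_scale * sds[[f]])
        pick <- clip_features(pick, clip_ranges)
        pick$weight <- pick$bmi * (pick$height / 100)^2
      }
      pick
    })
    added <- do.call(rbind, added)
    added$subject_id <- sprintf("A%06d", seq_len(nrow(added)))
    out <- rbind(records, added)
    rownames(out) <- NULL
    out
  })
}

#' Encode records as the 13-feature input matrix of the classifier
#'
#' Builds the fixed 13-column feature matrix
#' (org_rank, gender_male, gender_female, age, height, weight, bmi, bvp,
#' gsr, skt, valence, arousal, subject_index_scaled), standardizes each
#' column to zero mean and unit variance (constant columns are set to 0),
#' and encodes labels as neutral = 0, happy = 1, excited = 2, angry = 3.
#'
#' @param records Non-empty data frame of employee records.
#' @return List with `x` (n x 13 standardized matrix), `y` (integer labels
#'   0..3), and `feature_names`.
#' @export
emotion_feature_matrix <- function(records) {
  if (nrow(records) == 0) stop("`records` must be non-empty")
  need <- c("org_rank", "gender", "age", "height", "weight", "bmi",
            "bvp", "gsr", "skt", "valence", "arousal", "emotion")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyNA(records[need])) stop("missing feature values in `records`")
  n <- nrow(records)
  x <- cbind(org_rank = records$org_rank,
             gender_male = as.numeric(records$gender == "male"),
             gender_female = as.numeric(records$gender == "female"),
             age = records$age, height = records$height,
             weight = records$weight, bmi = records$bmi,
             bvp = records$bvp, gsr = records$gsr, skt = records$skt,
             valence = records$valence, arousal = records$arousal,
             subject_index_scaled = seq_len(n) / n)
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  x <- sweep(x, 2, mu)
  nz <- sd > 0
  x[, nz] <- sweep(x[, nz, drop = FALSE], 2, sd[nz], "/")
  x[, !nz] <- 0
  y <- match(records$emotion, emotion_levels()) - 1L
  if (anyNA(y)) stop("unknown emotion label in `records`")
  list(x = x, y = as.integer(y), feature_names = colnames(x))
}

#' Write employee records to a delimited text file
#'
#' Comma-separated, header row, UTF-8; numeric columns are written with 15
#' significant digits so that a read/write round trip is lossless at that
#' precision.
#'
#' @param records Data frame of employee records.
#' @param path Output file path.
#' @export
write_emotion_records <- function(records, path) {
  df <- records
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num))
    if (!is.integer(df[[j]])) df[[j]] <- sprintf("%.15g", df[[j]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read employee records written by [write_emotion_records()]
#' @param path CSV file path.
#' @return Data frame of employee records.
#' @export
read_emotion_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  df$org_rank <- as.integer(df$org_rank)
  df
}
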