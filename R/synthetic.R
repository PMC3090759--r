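#' Configuration for the synthetic profile generator
#'
#' The generator emulates the statistical structure of forensic mtDNA
#' population databases: four coarse population labels with the class
#' proportions of the FBI-style forensic table, haplogroups strongly but
#' imperfectly associated with the labels, founder polymorphism motifs per
#' haplogroup, per-sample private mutations, and laboratory-dependent typed
#' ranges. It makes no claim of coalescent realism: only the
#' association structure the classifiers exploit is modelled.
#'
#' Coverage models mimic how real databases are sequenced. Laboratories use a
#' limited repertoire of primer schemes, so typed ranges are drawn from a
#' small set of schemes rather than per-sample uniform endpoints:
#' `"full"` types everything; `"forensic_like"` always covers the cores
#' 16024-16365 and 73-340 with scheme-dependent extensions; and
#' `"published_like"` omits HVR2 entirely with probability `hvr2_missing`
#' (default 0.6) and HVR1 with probability `hvr1_missing` (default 0.05),
#' as observed in literature-derived tables.
#'
#' @param n_samples Number of samples (default 1000).
#' @param class_labels Population labels; default the four coarse groups
#'   Caucasian, African, Asian, Hispanic.
#' @param class_proportions Sampling proportions, summing to 1; default the
#'   forensic-table composition (0.378, 0.295, 0.172, 0.155).
#' @param n_haplogroups Number of haplogroups (default 23 basal groups).
#' @param mixing Class x haplogroup stochastic matrix (rows sum to 1); NULL
#'   builds a default where each class concentrates `mixing_concentration` of
#'   its mass on its own haplogroup block.
#' @param mixing_concentration Probability mass a class places on its own
#'   haplogroups in the default mixing (default 0.85).
#' @param motif_size Founder polymorphisms per haplogroup motif (default 6).
#' @param motif_overlap Expected number of polymorphisms shared by two motifs
#'   (default 1; 0 makes motifs pairwise disjoint).
#' @param motif_region [region_set()] the motif positions are drawn from
#'   (default: the whole HVR universe).
#' @param private_rate Poisson mean of per-sample private substitutions
#'   (default 2).
#' @param coverage_model One of `"full"`, `"forensic_like"`,
#'   `"published_like"`.
#' @param hvr2_missing,hvr1_missing Missing-region probabilities for the
#'   published-like coverage model.
#' @param reference_like_class Optional label whose motifs are empty, making
#'   its samples rCRS-like (exercises the reference-imputation bias).
#' @param seed Integer seed; one stream drives all draws in documented order
#'   (motifs, then per-sample class, haplogroup, privates, coverage).
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 1000,
                             class_labels = c("Caucasian", "African", "Asian", "Hispanic"),
                             class_proportions = c(0.378, 0.295, 0.172, 0.155),
                             n_haplogroups = 23,
                             mixing = NULL,
                             mixing_concentration = 0.85,
                             motif_size = 6,
                             motif_overlap = 1,
                             motif_region = NULL,
                             private_rate = 2,
                             coverage_model = c("full", "forensic_like", "published_like"),
                             hvr2_missing = 0.6,
                             hvr1_missing = 0.05,
                             reference_like_class = NULL,
                             seed = 1) {
  coverage_model <- match.arg(coverage_model)
  stopifnot(
    length(class_labels) >= 2,
    length(class_proportions) == length(class_labels),
    n_haplogroups >= length(class_labels) || !is.null(mixing),
    motif_size >= 1, motif_overlap >= 0, private_rate >= 0
  )
  if (abs(sum(class_proportions) - 1) > 1e-12) {
    stop("synthetic_config: class_proportions must sum to 1")
  }
  if (is.null(mixing)) {
    mixing <- default_mixing(length(class_labels), n_haplogroups, mixing_concentration)
  }
  if (nrow(mixing) != length(class_labels) || ncol(mixing) != n_haplogroups) {
    stop("synthetic_config: mixing must be |classes| x n_haplogroups")
  }
  if (any(abs(rowSums(mixing) - 1) > 1e-12)) {
    stop("synthetic_config: mixing rows must sum to 1")
  }
  if (is.null(motif_region)) {
    motif_region <- region_set(c(HVR1_START, HVR2_START), c(HVR1_END, HVR2_END))
  }
  if (!is.null(reference_like_class) &&
    !(reference_like_class %in% class_labels)) {
    stop("synthetic_config: reference_like_class not among class_labels")
  }
  structure(
    list(
      n_samples = as.integer(n_samples), class_labels = class_labels,
      class_proportions = class_proportions,
      n_haplogroups = as.integer(n_haplogroups), mixing = mixing,
      motif_size = as.integer(motif_size), motif_overlap = motif_overlap,
      motif_region = motif_region, private_rate = private_rate,
      coverage_model = coverage_model,
      hvr2_missing = hvr2_missing, hvr1_missing = hvr1_missing,
      reference_like_class = reference_like_class, seed = as.integer(seed)
    ),
    class = "synthetic_config"
  )
}

# each class gets a contiguous block of haplogroups, sized proportionally to
# the class proportions; `conc` of each row's mass is uniform over the class's
# own block, the remainder uniform over all other haplogroups
default_mixing <- function(n_classes, n_haplogroups, conc) {
  share <- rep(n_haplogroups %/% n_classes, n_classes)
  extra <- n_haplogroups %% n_classes
  if (extra > 0) share[seq_len(extra)] <- share[seq_len(extra)] + 1L
  stops <- cumsum(share)
  starts <- stops - share + 1L
  mix <- matrix(0, nrow = n_classes, ncol = n_haplogroups)
  for (g in seq_len(n_classes)) {
    own <- starts[g]:stops[g]
    mix[g, own] <- conc / length(own)
    mix[g, -own] <- (1 - conc) / (n_haplogroups - length(own))
  }
  mix
}

#' Generate haplogroup founder motifs
#'
#' Draws each haplogroup's motif as `motif_size` substitution tokens at
#' positions sampled from a shared pool sized so two motifs share
#' `motif_overlap` polymorphisms in expectation (pool size
#' `motif_size^2 / motif_overlap`); with `motif_overlap = 0` all motifs are
#' pairwise disjoint. Deterministic given the config seed.
#'
#' @param config A [synthetic_config()].
#' @return Named list: one character vector of tokens per haplogroup
#'   (`"HG01"`, `"HG02"`, ...).
#' @export
generate_motifs <- function(config) {
  with_seed(config$seed, draw_motifs(config))
}

draw_motifs <- function(config) {
  positions <- region_positions(config$motif_region)
  k <- config$n_haplogroups
  s <- config$motif_size
  if (config$motif_overlap == 0) {
    if (k * s > length(positions)) {
      stop("generate_motifs: motif universe too small for disjoint motifs")
    }
    pool <- sample(positions, k * s)
    chunks <- split(pool, rep(seq_len(k), each = s))
  } else {
    pool_size <- max(s + 1, round(s^2 / config$motif_overlap))
    if (pool_size > length(positions)) {
      stop("generate_motifs: motif universe too small for requested overlap")
    }
    pool <- sample(positions, pool_size)
    chunks <- lapply(seq_len(k), function(i) sample(pool, s))
  }
  motifs <- lapply(chunks, function(pos) {
    paste0(pos, sample(c("A", "C", "G", "T"), length(pos), replace = TRUE))
  })
  names(motifs) <- sprintf("HG%02d", seq_len(k))
  motifs
}

region_positions <- function(rs) {
  unlist(lapply(seq_len(nrow(rs)), function(i) rs$start[i]:rs$end[i]))
}

# ---- coverage schemes -------------------------------------------------------
# a scheme is a region_set; labs reuse a small repertoire of primer designs,
# which also makes common-region model caching effective

forensic_schemes <- function() {
  list(
    region_set(c(16024, 73), c(16365, 340)), # core only
    region_set(c(16024, 73), c(16400, 400)),
    region_set(c(16024, 73), c(16569, 576)),
    region_set(c(16024, 1), c(16569, 576)), # full universe
    region_set(c(16024, 50), c(16450, 450))
  )
}
FORENSIC_SCHEME_PROBS <- c(0.35, 0.2, 0.2, 0.15, 0.1)

hvr1_only_schemes <- function() {
  list(
    region_set(16024, 16365),
    region_set(16024, 16400),
    region_set(16090, 16365), # does not reach the 16024-16365 core start
    region_set(16024, 16569)
  )
}
HVR1_ONLY_PROBS <- c(0.4, 0.25, 0.2, 0.15)

hvr2_only_schemes <- function() {
  list(region_set(73, 340), region_set(1, 576))
}
HVR2_ONLY_PROBS <- c(0.7, 0.3)

draw_coverage <- function(model, n, hvr2_missing, hvr1_missing) {
  if (model == "full") {
    full <- region_set(c(16024, 1), c(16569, 576))
    return(rep(list(full), n))
  }
  if (model == "forensic_like") {
    schemes <- forensic_schemes()
    idx <- sample.int(length(schemes), n, replace = TRUE, prob = FORENSIC_SCHEME_PROBS)
    return(schemes[idx])
  }
  # published_like: mixture of HVR1-only, HVR2-only and both-region schemes
  u <- runif(n)
  out <- vector("list", n)
  h1 <- hvr1_only_schemes()
  h2 <- hvr2_only_schemes()
  both <- forensic_schemes()
  for (i in seq_len(n)) {
    out[[i]] <- if (u[i] < hvr2_missing) {
      h1[[sample.int(length(h1), 1, prob = HVR1_ONLY_PROBS)]]
    } else if (u[i] < hvr2_missing + hvr1_missing) {
      h2[[sample.int(length(h2), 1, prob = HVR2_ONLY_PROBS)]]
    } else {
      both[[sample.int(length(both), 1, prob = FORENSIC_SCHEME_PROBS)]]
    }
  }
  out
}

# ---- core generator ---------------------------------------------------------

# draws everything except typed ranges; consumes the active RNG stream
draw_core <- function(config) {
  n <- config$n_samples
  motifs <- draw_motifs(config)
  class_idx <- sample.int(length(config$class_labels), n,
    replace = TRUE, prob = config$class_proportions
  )
  hap_idx <- vapply(class_idx, function(g) {
    sample.int(config$n_haplogroups, 1, prob = config$mixing[g, ])
  }, 0L)
  labels <- config$class_labels[class_idx]
  haplogroups <- names(motifs)[hap_idx]
  axis <- hvr_axis()
  private <- vector("list", n)
  founder <- vector("list", n)
  for (i in seq_len(n)) {
    founder[[i]] <- if (!is.null(config$reference_like_class) &&
      labels[i] == config$reference_like_class) {
      character(0)
    } else {
      motifs[[hap_idx[i]]]
    }
    n_priv <- rpois(1, config$private_rate)
    private[[i]] <- if (n_priv > 0) {
      pos <- sample(axis, n_priv)
      paste0(pos, sample(c("A", "C", "G", "T"), n_priv, replace = TRUE))
    } else {
      character(0)
    }
  }
  list(
    sample_id = sprintf("S%05d", seq_len(n)),
    label = labels, haplogroup = haplogroups,
    founder = founder, private = private, motifs = motifs
  )
}

build_profiles <- function(core, idx, coverage) {
  lapply(seq_along(idx), function(j) {
    i <- idx[j]
    typed <- coverage[[j]]
    toks <- unique(c(core$founder[[i]], core$private[[i]]))
    if (length(toks) > 0) {
      pos <- parse_polymorphisms(toks)$position
      toks <- toks[region_contains(typed, pos)]
    }
    sample_profile(core$sample_id[i], typed, toks,
      label = core$label[i]
    )
  })
}

#' Generate a synthetic profile dataset
#'
#' Per sample: class from `class_proportions`, haplogroup from the class's
#' mixing row, polymorphisms = founder motif plus Poisson(`private_rate`)
#' private substitutions, typed ranges from the coverage model; polymorphisms
#' outside the typed ranges are removed. Byte-identical output for a fixed
#' seed.
#'
#' @param config A [synthetic_config()].
#' @return List with `dataset` (a valid [profile_dataset()]) and `truth`
#'   (data.frame `sample_id`, `label`, `haplogroup`, plus list columns
#'   `founder` and `private`).
#' @export
generate_dataset <- function(config) {
  with_seed(config$seed, {
    core <- draw_core(config)
    coverage <- draw_coverage(
      config$coverage_model, config$n_samples,
      config$hvr2_missing, config$hvr1_missing
    )
    dataset <- profile_dataset(build_profiles(core, seq_len(config$n_samples), coverage))
    truth <- data.frame(
      sample_id = core$sample_id, label = core$label,
      haplogroup = core$haplogroup, stringsAsFactors = FALSE
    )
    truth$founder <- core$founder
    truth$private <- core$private
    list(dataset = dataset, truth = truth, motifs = core$motifs)
  })
}

#' Train/test split emulating database assembly bias
#'
#' Splits one synthetic cohort into train and test, optionally removing a
#' class from the test set (as when a population is absent from
#' literature-derived databases) and re-drawing the test samples' typed ranges
#' from a different coverage model (e.g. `published_like` against a
#' `forensic_like` training set).
#'
#' @param config A [synthetic_config()]; its `coverage_model` applies to the
#'   training portion.
#' @param test_fraction Fraction of samples assigned to the test set.
#' @param drop_class_in_test Optional label removed from the test set.
#' @param test_coverage_model Coverage model for the test portion (default:
#'   the config's own).
#' @return List with `train`, `test` (both [profile_dataset()]s) and `truth`
#'   (as in [generate_dataset()], with a `split` column).
#' @export
make_biased_split <- function(config, test_fraction = 0.3,
                              drop_class_in_test = NULL,
                              test_coverage_model = NULL) {
  if (!is.null(drop_class_in_test) &&
    !(drop_class_in_test %in% config$class_labels)) {
    stop("make_biased_split: drop_class_in_test not among class labels")
  }
  if (is.null(test_coverage_model)) test_coverage_model <- config$coverage_model
  with_seed(config$seed, {
    core <- draw_core(config)
    n <- config$n_samples
    test_idx0 <- sort(sample.int(n, round(test_fraction * n)))
    train_idx <- setdiff(seq_len(n), test_idx0)
    # dropped samples are discarded, not recycled into training, so the
    # train composition stays an unbiased draw from the configured world
    test_idx <- if (is.null(drop_class_in_test)) {
      test_idx0
    } else {
      test_idx0[core$label[test_idx0] != drop_class_in_test]
    }
    if (length(test_idx) == 0) stop("make_biased_split: empty test set")
    cov_train <- draw_coverage(
      config$coverage_model, length(train_idx),
      config$hvr2_missing, config$hvr1_missing
    )
    cov_test <- draw_coverage(
      test_coverage_model, length(test_idx),
      config$hvr2_missing, config$hvr1_missing
    )
    split_col <- rep("train", n)
    split_col[test_idx0] <- "dropped" # re-marked below for retained samples
    split_col[test_idx] <- "test"
    truth <- data.frame(
      sample_id = core$sample_id, label = core$label,
      haplogroup = core$haplogroup, split = split_col,
      stringsAsFactors = FALSE
    )
    list(
      train = profile_dataset(build_profiles(core, train_idx, cov_train)),
      test = profile_dataset(build_profiles(core, test_idx, cov_test)),
      truth = truth
    )
  })
}
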