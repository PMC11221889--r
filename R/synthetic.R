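# Synthetic antigen-antibody mutation datasets with a known additive
# ground truth, so that training, evaluation and interpretation can be
# exercised end-to-end without external downloads.
#
# Each complex gets random wild-type chains, a contiguous antibody
# "interface" window, and a per-residue propensity scale v; a mutation
# a->b at site p contributes weight(p) * (v[b] - v[a]) kcal/mol to the
# label, plus Gaussian noise.  The effect table v[b] - v[a] is
# antisymmetric by construction and zero on the diagonal.

#' Synthetic dataset configuration
#'
#' Defaults define the package's standard synthetic benchmark: 8
#' complexes x 60 mutation records, antigen length 60-120, antibody
#' length 80-150, up to 5 point mutations per record, an 8-residue
#' antibody interface window, and 0.3 kcal/mol label noise.
#'
#' @param n_complexes Number of distinct complexes.
#' @param mutations_per_complex Mutation records per complex.
#' @param antigen_length_range,antibody_length_range Inclusive length
#'   ranges for the wild-type chains.
#' @param max_points_per_mutation Upper bound on point mutations per
#'   record (>= 1; each record draws 1..max uniformly).
#' @param interface_width Width of the contiguous antibody window whose
#'   positions carry effect weight 1 (all other positions weigh 0).
#' @param interface_bias Probability that a mutation site is drawn from
#'   the interface window.
#' @param noise_sd Gaussian label noise, kcal/mol.
#' @param seed Generator seed.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_complexes = 8L, mutations_per_complex = 60L,
                             antigen_length_range = c(60L, 120L),
                             antibody_length_range = c(80L, 150L),
                             max_points_per_mutation = 5L,
                             interface_width = 8L, interface_bias = 0.8,
                             noise_sd = 0.3, seed = 7L) {
  stopifnot(n_complexes >= 1, mutations_per_complex >= 1,
            length(antigen_length_range) == 2L,
            antigen_length_range[1] >= 1,
            diff(antigen_length_range) >= 0,
            length(antibody_length_range) == 2L,
            antibody_length_range[1] >= 1,
            diff(antibody_length_range) >= 0,
            max_points_per_mutation >= 1,
            interface_width >= 1,
            interface_bias >= 0, interface_bias <= 1,
            noise_sd >= 0)
  if (interface_width > antibody_length_range[1])
    stop("interface wider than the shortest antibody", call. = FALSE)
  structure(list(n_complexes = as.integer(n_complexes),
                 mutations_per_complex = as.integer(mutations_per_complex),
                 antigen_length_range = as.integer(antigen_length_range),
                 antibody_length_range = as.integer(antibody_length_range),
                 max_points_per_mutation = as.integer(max_points_per_mutation),
                 interface_width = as.integer(interface_width),
                 interface_bias = interface_bias,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

random_chain <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                  collapse = "")

#' Generate a synthetic mutation dataset with known ground truth
#'
#' @param cfg A [synthetic_config()].
#' @return List with `dataset` (a `mutation_dataset` in the canonical
#'   dialect, provenance `"synthetic"`) and `truth` (a `ground_truth`:
#'   the 20x20 per-substitution effect table, and per-complex interface
#'   positions and weights).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr::with_seed(cfg$seed, {
    v <- stats::rnorm(20L)
    names(v) <- AA_ALPHABET
    effect <- outer(v, v, function(a, b) b - a)  # effect[wt, mt]
    dimnames(effect) <- list(AA_ALPHABET, AA_ALPHABET)

    complexes <- list()
    rows <- list()
    for (c_i in seq_len(cfg$n_complexes)) {
      cid <- sprintf("SYN%02d", c_i)
      n_ag <- sample(cfg$antigen_length_range[1]:cfg$antigen_length_range[2], 1L)
      n_ab <- sample(cfg$antibody_length_range[1]:cfg$antibody_length_range[2], 1L)
      ag <- random_chain(n_ag)
      ab <- random_chain(n_ab)
      start <- sample.int(n_ab - cfg$interface_width + 1L, 1L)
      interface <- start:(start + cfg$interface_width - 1L)
      weights <- numeric(n_ab)
      weights[interface] <- 1
      complexes[[cid]] <- list(antibody = ab, antigen = ag,
                               interface = interface, weights = weights)
      ab_chars <- strsplit(ab, "")[[1]]
      for (m_i in seq_len(cfg$mutations_per_complex)) {
        n_pts <- sample.int(cfg$max_points_per_mutation, 1L)
        in_iface <- stats::runif(n_pts) < cfg$interface_bias
        pool_in <- interface
        pool_out <- setdiff(seq_len(n_ab), interface)
        sites <- integer(0)
        for (p in seq_len(n_pts)) {
          pool <- if (in_iface[p]) setdiff(pool_in, sites)
                  else setdiff(pool_out, sites)
          if (length(pool) == 0L) pool <- setdiff(seq_len(n_ab), sites)
          sites <- c(sites, pool[sample.int(length(pool), 1L)])
        }
        wt <- ab_chars[sites]
        mt <- vapply(wt, function(w)
          sample(setdiff(AA_ALPHABET, w), 1L), character(1))
        signal <- sum(weights[sites] * effect[cbind(wt, mt)])
        ddg <- signal + stats::rnorm(1L, 0, cfg$noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          complex_id = cid, ab_chains = "H", ag_chains = "A",
          ab_seq = ab, ag_seq = ag,
          mutations = paste(sprintf("H:%s%d%s", wt, sites, mt),
                            collapse = ","),
          ddg = ddg, stringsAsFactors = FALSE)
      }
    }
  })
  dataset <- new_mutation_dataset(do.call(rbind, rows),
                                  name = "synthetic", provenance = "synthetic")
  truth <- structure(list(effect = effect, complexes = complexes,
                          config = cfg), class = "ground_truth")
  list(dataset = dataset, truth = truth)
}

#' Noise-free additive signal for a record under the generator's truth
#'
#' @param record A record from [dataset_record()] of a generated
#'   dataset.
#' @param truth The `ground_truth` returned by [generate_dataset()].
#' @return The additive ddG signal in kcal/mol (label minus noise).
#' @export
ground_truth_ddg <- function(record, truth) {
  stopifnot(inherits(truth, "ground_truth"))
  cx <- truth$complexes[[record$complex_id]]
  if (is.null(cx))
    stop("unknown complex '", record$complex_id, "'", call. = FALSE)
  muts <- record$mutations
  if (nrow(muts) == 0L) return(0)
  if (any(muts$pos < 1L | muts$pos > length(cx$weights)))
    stop("mutation site outside the known complex", call. = FALSE)
  sum(cx$weights[muts$pos] * truth$effect[cbind(muts$wt, muts$mt)])
}
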