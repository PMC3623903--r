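#' Configuration for the synthetic annotated-sequence generator
#'
#' The generator plants homologous domain families: each family has a
#' random prototype sequence; every domain instance is a copy of its
#' family prototype, trimmed by a few residues at each end (emulating the
#' assignment uncertainty of real domain boundaries) and point-mutated at
#' `mutation_rate`. Chains alternate random linkers and domain instances,
#' with short unstructured tails at both chain ends. Shape strings emit
#' helix/strand-like symbols (`A,T,G,K`) inside domains and loop-like
#' symbols (`R,S,U,V`) elsewhere, each flipped to a uniformly random
#' symbol with probability `shape_noise`. Default length ranges are chosen
#' so that the boundary:domain residue ratio is about 1:15, the imbalance
#' regime of real domain-annotated chains.
#'
#' @param seed Integer seed; every output is a deterministic function of it.
#' @param n_families Number of domain families.
#' @param n_ref,n_query Reference and query chain counts.
#' @param domain_len_range,linker_len_range,tail_len_range Integer ranges
#'   (min, max) for prototype, inter-domain linker, and terminal tail
#'   lengths.
#' @param domains_per_chain_weights Probabilities of 1, 2, 3 domains per
#'   chain (must sum to 1).
#' @param mutation_rate Per-residue substitution probability in `[0, 0.5]`.
#' @param shape_noise Probability a shape symbol is randomized.
#' @param boundary_jitter Maximum residues trimmed from each end of a
#'   domain instance (trim drawn uniformly from `0..boundary_jitter`).
#' @param R Hinge half-width used for the reference three-state labels.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_families = 3L, n_ref = 300L,
                         n_query = 150L,
                         domain_len_range = c(120L, 220L),
                         linker_len_range = c(6L, 18L),
                         tail_len_range = c(0L, 7L),
                         domains_per_chain_weights = c(0.5, 0.35, 0.15),
                         mutation_rate = 0.05, shape_noise = 0.1,
                         boundary_jitter = 8L, R = 10L) {
  stopifnot(domain_len_range[1L] >= 1L,
            domain_len_range[1L] <= domain_len_range[2L],
            linker_len_range[1L] >= 1L,
            linker_len_range[1L] <= linker_len_range[2L],
            tail_len_range[1L] >= 0L,
            tail_len_range[1L] <= tail_len_range[2L],
            mutation_rate >= 0, mutation_rate <= 0.5,
            shape_noise >= 0, shape_noise <= 1,
            boundary_jitter >= 0L,
            abs(sum(domains_per_chain_weights) - 1) < 1e-9)
  structure(list(seed = as.integer(seed), n_families = as.integer(n_families),
                 n_ref = as.integer(n_ref), n_query = as.integer(n_query),
                 domain_len_range = as.integer(domain_len_range),
                 linker_len_range = as.integer(linker_len_range),
                 tail_len_range = as.integer(tail_len_range),
                 domains_per_chain_weights = domains_per_chain_weights,
                 mutation_rate = mutation_rate, shape_noise = shape_noise,
                 boundary_jitter = as.integer(boundary_jitter),
                 R = as.integer(R)),
            class = "synth_config")
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P",
          "S","T","W","Y","V")
SHAPE_DOMAIN <- c("A", "T", "G", "K")
SHAPE_LOOP <- c("R", "S", "U", "V")

random_aa <- function(n) sample(AA20, n, replace = TRUE)

mutate_aa <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit],
                         function(a) sample(setdiff(AA20, a), 1L), "")
  chars
}

#' Generate family prototype sequences
#'
#' Draws `n_families` random amino-acid strings with lengths uniform in
#' `domain_len_range`. Seeds the RNG from `cfg$seed`, so the prototypes
#' are a pure function of the configuration.
#'
#' @param cfg A [synth_config()].
#' @return Character vector of prototype sequences.
#' @export
generate_family_prototypes <- function(cfg) {
  set.seed(cfg$seed)
  lens <- sample(cfg$domain_len_range[1L]:cfg$domain_len_range[2L],
                 cfg$n_families, replace = TRUE)
  vapply(lens, function(l) paste(random_aa(l), collapse = ""), "")
}

#' Generate one annotated chain
#'
#' Consumes the current RNG state (callers seed once per dataset). The
#' chain is tail + domain (+ linker + domain ...) + tail; each domain is a
#' trimmed, mutated copy of a randomly chosen family prototype.
#'
#' @param cfg A [synth_config()].
#' @param prototypes Prototypes from [generate_family_prototypes()].
#' @return List with `sequence`, `annotation` (a [domain_annotation()]),
#'   `shape` (a [shape_string()]), and `families` (prototype index per
#'   domain).
#' @export
generate_annotated_chain <- function(cfg, prototypes) {
  n_dom <- sample.int(length(cfg$domains_per_chain_weights), 1L,
                      prob = cfg$domains_per_chain_weights)
  fams <- sample.int(length(prototypes), n_dom, replace = TRUE)
  rint <- function(rng) if (rng[1L] == rng[2L]) rng[1L] else
    sample(rng[1L]:rng[2L], 1L)

  seq_chars <- character(0)
  shape_chars <- character(0)
  segments <- list()
  add_loop <- function(n) {
    seq_chars <<- c(seq_chars, random_aa(n))
    shape_chars <<- c(shape_chars, sample(SHAPE_LOOP, n, replace = TRUE))
  }
  add_loop(rint(cfg$tail_len_range))
  for (d in seq_len(n_dom)) {
    proto <- strsplit(prototypes[fams[d]], "")[[1L]]
    kN <- rint(c(0L, cfg$boundary_jitter))
    kC <- rint(c(0L, cfg$boundary_jitter))
    inst <- mutate_aa(proto[(1L + kN):(length(proto) - kC)],
                      cfg$mutation_rate)
    segments[[d]] <- c(length(seq_chars) + 1L,
                       length(seq_chars) + length(inst))
    seq_chars <- c(seq_chars, inst)
    shape_chars <- c(shape_chars,
                     sample(SHAPE_DOMAIN, length(inst), replace = TRUE))
    if (d < n_dom) add_loop(rint(cfg$linker_len_range))
  }
  add_loop(rint(cfg$tail_len_range))

  if (cfg$shape_noise > 0) {
    flip <- stats::runif(length(shape_chars)) < cfg$shape_noise
    if (any(flip))
      shape_chars[flip] <- sample(SHAPE_ALPHABET, sum(flip), replace = TRUE)
  }
  ann <- domain_annotation("chain", length(seq_chars),
                           lapply(segments, function(s) cbind(s[1L], s[2L])))
  list(sequence = paste(seq_chars, collapse = ""),
       annotation = ann,
       shape = shape_string(shape_chars),
       families = fams)
}

#' Generate a complete reference database plus query set
#'
#' Produces `n_ref` labeled reference chains and `n_query` disjoint query
#' chains drawn from the same families (so alignment recovers informative
#' DHB profiles). Queries exactly matching a reference sequence are
#' resampled, so the exact-match exclusion filter never removes reference
#' entries. Three-state labels use the hinge half-width `cfg$R`.
#'
#' @param cfg A [synth_config()].
#' @return List with `reference` (list of `reference_entry`), `queries`
#'   (list of chains, each with `id`, `sequence`, `annotation`, `shape`,
#'   `labels2`, `labels3`), and `prototypes`.
#' @export
generate_dataset <- function(cfg) {
  prototypes <- generate_family_prototypes(cfg)
  hcfg <- hinge_config(cfg$R)
  make_chain <- function(id) {
    ch <- generate_annotated_chain(cfg, prototypes)
    ch$annotation$chain_id <- id
    ch$labels2 <- assign_two_state_labels(ch$annotation)
    ch$labels3 <- assign_hinge_labels(ch$labels2, ch$annotation, hcfg)
    ch$id <- id
    ch
  }
  reference <- lapply(sprintf("ref%04d", seq_len(cfg$n_ref)), make_chain)
  ref_seqs <- vapply(reference, `[[`, "", "sequence")
  queries <- lapply(sprintf("qry%04d", seq_len(cfg$n_query)), function(id) {
    for (attempt in 1:100) {
      ch <- make_chain(id)
      if (!ch$sequence %in% ref_seqs) return(ch)
    }
    stop("could not generate a query distinct from all references; ",
         "increase mutation_rate")
  })
  list(reference = lapply(reference, function(ch)
         reference_entry(ch$id, ch$sequence, ch$labels3)),
       queries = queries,
       prototypes = prototypes)
}

#' Write a generated dataset as a fixture directory
#'
#' Emits the same formats the pipeline reads: `reference.fasta` +
#' `reference_labels.tsv` (the database), `queries.fasta`,
#' `query_annotations.tsv`, `query_shapes.tsv`, and
#' `query_labels{2,3}.tsv` (truth labels).
#'
#' @param dataset A [generate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @export
write_fixture <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  db <- build_reference_db(dataset$reference)
  write_reference_db(db, file.path(dir, "reference.fasta"),
                     file.path(dir, "reference_labels.tsv"))
  qseqs <- Biostrings::AAStringSet(
    vapply(dataset$queries, `[[`, "", "sequence"))
  names(qseqs) <- vapply(dataset$queries, `[[`, "", "id")
  Biostrings::writeXStringSet(qseqs, file.path(dir, "queries.fasta"))
  write_annotations(lapply(dataset$queries, `[[`, "annotation"),
                    file.path(dir, "query_annotations.tsv"))
  shapes <- lapply(dataset$queries, function(q) q$shape)
  names(shapes) <- names(qseqs)
  write_shapes(shapes, file.path(dir, "query_shapes.tsv"))
  l2 <- lapply(dataset$queries, `[[`, "labels2")
  l3 <- lapply(dataset$queries, `[[`, "labels3")
  names(l2) <- names(l3) <- names(qseqs)
  write_labels(l2, file.path(dir, "query_labels2.tsv"))
  write_labels(l3, file.path(dir, "query_labels3.tsv"))
  invisible(dir)
}
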