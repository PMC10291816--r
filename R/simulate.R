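# Synthetic-data generator.  Ground truth is a multiplicative bias model:
# each primer pair (v, j) amplifies with relative efficiency
# exp(v_effect + j_effect + interaction), the structure the calibration
# measures.  ST counts are NB-distributed around pair means with common
# overdispersion d (default 0.125, the published calibration value);
# clonotype counts inherit the same pair bias.  Read emission embeds the
# barcodes in 200-nt templates so the whole pipeline round-trips.

# Deterministic sub-seed derivation so one user seed drives every stage
# without reuse; kept below 2^31 - 1.
sub_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k) %% 1000L
}

#' Ground-truth primer-pair bias model
#'
#' Draws centered normal log-efficiencies for the 20 V primers, the 13 J
#' primers and their 260 interactions.  Pair (v, j) has relative
#' efficiency `exp(v_effect[v] + j_effect[j] + interaction[v, j])`.
#' Defaults give a multi-fold ST-to-ST spread comparable to real
#' uncalibrated panels.
#'
#' @param seed integer seed (model is deterministic given it).
#' @param v_sd,j_sd,interaction_sd standard deviations of the
#'   log-efficiency components (>= 0; 0 switches a component off).
#' @return an object of class `bias_model`.
#' @export
make_bias_model <- function(seed, v_sd = 0.6, j_sd = 0.6,
                            interaction_sd = 0.2) {
  stopifnot(v_sd >= 0, j_sd >= 0, interaction_sd >= 0)
  set.seed(seed)
  center <- function(x) x - mean(x)
  v <- center(rnorm(N_V, 0, v_sd))
  j <- center(rnorm(N_J, 0, j_sd))
  int <- matrix(center(rnorm(N_V * N_J, 0, interaction_sd)), N_V, N_J)
  if (v_sd == 0) v[] <- 0
  if (j_sd == 0) j[] <- 0
  if (interaction_sd == 0) int[] <- 0
  structure(list(v_effects = v, j_effects = j, interaction = int),
            class = "bias_model")
}

#' Relative pair efficiencies and true scaling factors of a bias model
#'
#' @param model a `bias_model`.
#' @return `bias_model_weights`: named length-260 vector of relative
#'   efficiencies (canonical template order); `true_scaling_factors`: the
#'   implied scaling factors, mean exactly 1.
#' @export
bias_model_weights <- function(model) {
  w <- exp(outer(model$v_effects, rep(1, N_J)) +
           outer(rep(1, N_V), model$j_effects) + model$interaction)
  setNames(as.numeric(t(w)), template_labels())  # row-major: v outer, j inner
}

#' @rdname bias_model_weights
#' @export
true_scaling_factors <- function(model) {
  w <- bias_model_weights(model)
  new_scaling_factors(w / mean(w), "true")
}

#' Simulate an ST-only count matrix
#'
#' Template i in every sample has mean `depth * w_i / sum(w)` (w = pair
#' efficiencies) and variance `m + d m^2`.  Two sampling schemes share
#' those NB marginals:
#' \describe{
#'   \item{`"independent"`}{every count is an independent NB draw -- the
#'     textbook model fitted to the calibration data.}
#'   \item{`"library"`}{each sample's total is one NB draw allocated
#'     multinomially across templates.  Binomial thinning of an NB
#'     leaves `d` unchanged, so per-template marginals are identical to
#'     the independent scheme, but the overdispersion is common-mode
#'     within a sample: templates rise and fall together, as observed in
#'     real ST-only batches (whose counts are demonstrably not
#'     independent).}
#' }
#'
#' @param model a `bias_model`.
#' @param n_samples number of replicate ST-only samples (default 20, the
#'   size of the reference calibration batch).
#' @param depth expected total ST count per sample (default 260 x 1000).
#' @param d NB overdispersion (default 0.125).
#' @param seed integer seed (mandatory).
#' @param allocation `"independent"` (default) or `"library"` (see
#'   above).
#' @return an `st_counts` matrix with attribute `"true_factors"` (the
#'   model's scaling factors).
#' @export
simulate_st_matrix <- function(model, n_samples = 20L, depth = 260000,
                               d = 0.125, seed,
                               allocation = c("independent", "library")) {
  if (missing(seed)) stop("seed is mandatory")
  allocation <- match.arg(allocation)
  stopifnot(d >= 0, depth > 0, n_samples >= 1)
  set.seed(seed)
  w <- bias_model_weights(model)
  mu <- depth * w / sum(w)
  if (allocation == "independent") {
    n <- N_TEMPLATES * n_samples
    counts <- if (d == 0) rpois(n, rep(mu, n_samples))
              else rnbinom(n, size = 1 / d, mu = rep(mu, n_samples))
    counts <- matrix(counts, nrow = N_TEMPLATES)
  } else {
    totals <- if (d == 0) rpois(n_samples, depth)
              else rnbinom(n_samples, size = 1 / d, mu = depth)
    counts <- vapply(totals, function(N)
      if (N == 0) integer(N_TEMPLATES)
      else as.integer(rmultinom(1, N, mu)), integer(N_TEMPLATES))
  }
  out <- st_count_matrix(counts)
  attr(out, "true_factors") <- true_scaling_factors(model)
  out
}

#' Simulate a ground-truth clonotype repertoire
#'
#' Clone abundances are log-normal (`sigma` = log-scale sd; 0 gives a
#' uniform repertoire), V/J genes are drawn uniformly from a panel of 21
#' V genes mapping many-to-one onto the 20 V primers (two genes share
#' primer 1, mirroring real panels) and 13 J genes mapping one-to-one,
#' and CDR3 sequences are random 36-45-mers.
#'
#' @param n_clones number of clonotypes (>= 1).
#' @param sigma log-normal shape of the abundance distribution.
#' @param seed integer seed (mandatory).
#' @return a list with `table` (clonotype data.frame whose `count` column
#'   holds the true relative abundances, summing to 1) and `map` (the
#'   matching primer map).
#' @export
simulate_repertoire <- function(n_clones, sigma = 1, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(n_clones >= 1, sigma >= 0)
  set.seed(seed)
  v_genes <- sprintf("TRBV%d", 1:21)
  j_genes <- sprintf("TRBJ%d", 1:13)
  map <- rbind(
    data.frame(gene = v_genes, segment = "V",
               primer_index = c(1L, seq_len(N_V))),  # TRBV1/2 share primer 1
    data.frame(gene = j_genes, segment = "J", primer_index = seq_len(N_J))
  )
  abundance <- rlnorm(n_clones, 0, sigma)
  repeat {
    cdr3 <- random_dna(n_clones, sample(36:45, n_clones, replace = TRUE))
    v <- sample(v_genes, n_clones, replace = TRUE)
    j <- sample(j_genes, n_clones, replace = TRUE)
    if (!anyDuplicated(paste(cdr3, v, j))) break
  }
  table <- data.frame(
    clonotype_id = sprintf("clone%04d", seq_len(n_clones)),
    cdr3_nt = cdr3, v_gene = v, j_gene = j,
    count = abundance / sum(abundance)
  )
  list(table = table, map = validate_primer_map(map))
}

#' Simulate one sequenced sample: ST / gDNA competition and pair bias
#'
#' The expected read budget `depth` is split between the ST mix and the
#' clonotypes proportionally to `st_mass` and `gdna_mass` (emulating the
#' template competition seen across an ST dilution ladder).  Within each
#' stream, expected counts are proportional to true abundance times the
#' pair efficiency (clonotypes inherit the bias of their primer pair,
#' the protocol's central working assumption; `bias_mismatch_sd` adds
#' clone-level log-normal departures from it to stress-test that
#' assumption).  All counts are NB with overdispersion `d`; dropouts
#' arise naturally at low expected counts.
#'
#' The sample is drawn as an NB total with overdispersion `d` allocated
#' multinomially across ST templates and clones.  Binomial thinning of an
#' NB leaves the dispersion parameter unchanged, so every individual
#' count is still marginally NB(mean, d) -- but the overdispersion is
#' common-mode within the library, so within-sample count *ratios* are
#' multinomial-tight.  This mirrors real libraries, where template
#' counts rise and fall together across samples rather than varying
#' independently.
#'
#' @param truth result of [simulate_repertoire()] (list with `table` and
#'   `map`).
#' @param model a `bias_model`.
#' @param depth expected total reads for the sample.
#' @param st_mass,gdna_mass relative input masses of the ST mix and
#'   genomic DNA (`st_mass = 0` gives a no-spike-in sample).
#' @param d NB overdispersion.
#' @param bias_mismatch_sd sd of clone-level log-bias departures from
#'   the pair efficiency (0 = bias identical to the ST's).
#' @param seed integer seed (mandatory).
#' @return a list with `table` (the truth table with `count` replaced by
#'   observed integer counts) and `st_counts` (named length-260 integer
#'   vector).
#' @export
simulate_experiment <- function(truth, model, depth = 1e5,
                                st_mass = 1, gdna_mass = 1, d = 0.125,
                                bias_mismatch_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(st_mass >= 0, gdna_mass >= 0, st_mass + gdna_mass > 0,
            d >= 0, depth > 0)
  set.seed(seed)
  w <- bias_model_weights(model)
  st_share <- st_mass / (st_mass + gdna_mass)
  tab <- truth$table
  idx <- .pair_index(tab, truth$map)
  if (any(is.na(idx))) stop("truth table contains genes absent from its map")
  b <- w[idx]
  if (bias_mismatch_sd > 0) b <- b * rlnorm(nrow(tab), 0, bias_mismatch_sd)
  a <- tab$count * b
  # category probabilities: ST templates, then clonotypes
  probs <- c(st_share * w / sum(w), (1 - st_share) * a / sum(a))
  total <- if (d == 0) rpois(1, depth)
           else rnbinom(1, size = 1 / d, mu = depth)
  counts <- if (total == 0) integer(length(probs))
            else as.integer(rmultinom(1, total, probs))
  st_counts <- setNames(counts[seq_len(N_TEMPLATES)], template_labels())
  tab$count <- counts[-seq_len(N_TEMPLATES)]
  list(table = tab, st_counts = st_counts)
}

# Random flanks are re-drawn until the assembled sequence has no window
# within `max_edits` of the universal barcode in either orientation, so
# error-free non-ST reads can never be flagged as ST.
.safe_flanks <- function(core, universal, left_len, right_len, max_edits = 1L) {
  repeat {
    seq <- paste0(random_dna(1, left_len), core, random_dna(1, right_len))
    if (.cpp_infix_find(seq, universal, max_edits)[["found"]] == 0L &&
        .cpp_infix_find(.cpp_revcomp(seq), universal, max_edits)[["found"]] == 0L)
      return(seq)
  }
}

revcomp_chr <- function(x) .cpp_revcomp(x)

#' Emit sequencing reads for simulated ST and clonotype counts
#'
#' One read per counted molecule.  ST reads are the template's fixed
#' 200-nt sequence: a left flank, the universal 9-nt barcode, the
#' pair-specific 16-nt barcode, and a right flank.  Clonotype reads embed
#' the clone's CDR3 between clone-specific flanks screened to contain no
#' near-match to the universal barcode.  Substitution errors are applied
#' per base at `error_rate` (optionally indels at `indel_rate`), and
#' roughly half the reads are emitted reverse-complemented.  With
#' `error_rate = 0` demultiplexing recovers the ST counts exactly.
#'
#' @param st_counts named length-260 integer vector of ST molecule counts.
#' @param table clonotype data.frame with observed integer `count`s (may
#'   be `NULL` for an ST-only sample).
#' @param library an `st_barcode_library`.
#' @param error_rate per-base substitution probability.
#' @param indel_rate per-read probability of a single random indel.
#' @param seed integer seed (mandatory; output is byte-reproducible).
#' @param path optional FASTQ output path; qualities are constant.
#' @return invisibly, a data.frame with `read_id` and `sequence` (also
#'   written to `path` if given).  Read ids encode the true origin
#'   (`ST:V03J05:7` or `CL:clone0001:2`).
#' @export
emit_reads <- function(st_counts, table, library, error_rate = 0.001,
                       indel_rate = 0, seed, path = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  validate_barcode_library(library)
  stopifnot(length(st_counts) == N_TEMPLATES, all(st_counts >= 0))
  set.seed(seed)
  labs <- template_labels()
  uni <- library$universal_barcode
  # fixed per-template 200-nt ST sequence: 40-nt flank + 9 + 16 + 135-nt flank
  st_tpl <- vapply(seq_len(N_TEMPLATES), function(i) {
    fl <- random_dna(1, 40)
    fr <- random_dna(1, 135)
    paste0(fl, uni, library$entries$unique_barcode[i], fr)
  }, character(1))
  ids <- character(0); seqs <- character(0)
  nz <- which(st_counts > 0)
  if (length(nz)) {
    ids <- sprintf("ST:%s:%d", rep(labs[nz], st_counts[nz]),
                   sequence(st_counts[nz]))
    seqs <- rep(st_tpl[nz], st_counts[nz])
  }
  if (!is.null(table) && nrow(table) > 0) {
    stopifnot(all(table$count >= 0))
    cl_seq <- vapply(seq_len(nrow(table)), function(k) {
      if (table$count[k] == 0) return(NA_character_)
      .safe_flanks(table$cdr3_nt[k], uni, 55L,
                   max(10L, 150L - 55L - nchar(table$cdr3_nt[k])))
    }, character(1))
    nzc <- which(table$count > 0)
    if (length(nzc)) {
      ids <- c(ids, sprintf("CL:%s:%d",
                            rep(table$clonotype_id[nzc], table$count[nzc]),
                            sequence(table$count[nzc])))
      seqs <- c(seqs, rep(cl_seq[nzc], table$count[nzc]))
    }
  }
  if (length(seqs)) {
    seqs <- .mutate_reads(seqs, error_rate, indel_rate)
    flip <- seq_along(seqs) %% 2L == 0L
    seqs[flip] <- revcomp_chr(seqs[flip])
  }
  out <- data.frame(read_id = ids, sequence = seqs)
  if (!is.null(path)) {
    dna <- Biostrings::DNAStringSet(setNames(out$sequence, out$read_id))
    qual <- Biostrings::PhredQuality(
      vapply(nchar(out$sequence), function(n)
        paste(rep("I", n), collapse = ""), character(1)))
    Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  }
  invisible(out)
}

.mutate_reads <- function(seqs, error_rate, indel_rate) {
  if (error_rate > 0) {
    seqs <- vapply(seqs, function(s) {
      n <- nchar(s)
      hits <- which(runif(n) < error_rate)
      if (length(hits)) {
        ch <- strsplit(s, "")[[1]]
        ch[hits] <- vapply(ch[hits], function(b)
          sample(setdiff(DNA_BASES, b), 1), character(1))
        s <- paste(ch, collapse = "")
      }
      s
    }, character(1), USE.NAMES = FALSE)
  }
  if (indel_rate > 0) {
    do_indel <- runif(length(seqs)) < indel_rate
    seqs[do_indel] <- vapply(seqs[do_indel], function(s) {
      n <- nchar(s)
      pos <- sample(n, 1)
      if (runif(1) < 0.5)
        paste0(substr(s, 1, pos - 1), substr(s, pos + 1, n))        # deletion
      else
        paste0(substr(s, 1, pos), sample(DNA_BASES, 1), substr(s, pos + 1, n))
    }, character(1), USE.NAMES = FALSE)
  }
  seqs
}
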