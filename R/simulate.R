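#' Configuration for the synthetic amplicon simulator
#'
#' Describes the conditions the simulator emulates: a V3-V4-like insert
#' (default 460 nt), taxa related by a tree with edge lengths in
#' generations, neutral substitution at `per_position_rate` per position per
#' generation (default `0.5e-9`), pyrosequencing-style homopolymer indels
#' injected per read at `homopolymer_indel_rate` per tract of length >= 3,
#' and a simple linear quality profile (error probability rising from
#' `mean_error` at the 5' end to `mean_error * (1 + decay)` at the 3' end).
#'
#' @param insert_length insert length in nucleotides (default 460).
#' @param n_taxa number of taxa when `tree` is `NULL`.
#' @param tree an [ape] `phylo` with edge lengths in generations, or `NULL`
#'   for a random topology with edge lengths drawn uniformly from
#'   `edge_range`.
#' @param edge_range range (generations) for random edge lengths; default
#'   `c(2.5e8, 1e9)`, giving pairwise separations of order 1e9 generations.
#' @param per_position_rate substitution probability per position per
#'   generation.
#' @param homopolymer_indel_rate probability of a +/-1-base indel per
#'   homopolymer tract (run of >= 3 identical bases) per read.
#' @param reads_per_taxon reads emitted per taxon.
#' @param mean_error,error_decay quality profile parameters.
#' @param fwd_primer,rev_primer primer pair flanking the insert in emitted
#'   reads.
#' @param seed RNG seed; mandatory determinism for fixtures.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(insert_length = 460L, n_taxa = 6L, tree = NULL,
                       edge_range = c(2.5e8, 1e9),
                       per_position_rate = 0.5e-9,
                       homopolymer_indel_rate = 0,
                       reads_per_taxon = 20L,
                       mean_error = 0.002, error_decay = 1,
                       fwd_primer = "TCCTACGGGAGGCAGCAGT",
                       rev_primer = "GGACTACCAGGGTATCTAATCCTGTT",
                       seed = 1L) {
  stopifnot_scalar_prob(per_position_rate, "per_position_rate")
  stopifnot_scalar_prob(homopolymer_indel_rate, "homopolymer_indel_rate")
  stopifnot_scalar_prob(mean_error, "mean_error")
  if (insert_length < 3) stop("`insert_length` must be >= 3", call. = FALSE)
  if (!is.null(tree) && !inherits(tree, "phylo"))
    stop("`tree` must be an ape phylo or NULL", call. = FALSE)
  structure(list(insert_length = as.integer(insert_length),
                 n_taxa = if (is.null(tree)) as.integer(n_taxa)
                          else length(tree$tip.label),
                 tree = tree, edge_range = edge_range,
                 per_position_rate = per_position_rate,
                 homopolymer_indel_rate = homopolymer_indel_rate,
                 reads_per_taxon = as.integer(reads_per_taxon),
                 mean_error = mean_error, error_decay = error_decay,
                 fwd_primer = toupper(fwd_primer),
                 rev_primer = toupper(rev_primer),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Substitute each position with probability p_sub to a uniformly chosen
# different base; returns the mutated integer-coded sequence.
.mutate_codes <- function(codes, p_sub) {
  hit <- which(stats::runif(length(codes)) < p_sub)
  if (length(hit)) {
    shift <- sample.int(3L, length(hit), replace = TRUE)
    codes[hit] <- (codes[hit] + shift) %% 4L
  }
  codes
}

.codes_to_seq <- function(codes) {
  paste(c("A", "C", "G", "T")[codes + 1L], collapse = "")
}

#' Simulate taxa diverging on a tree
#'
#' Draws a random ancestral insert and evolves it along each tree edge: over
#' `g` generations each position substitutes with probability
#' `1 - (1 - r)^g` to a uniformly chosen different base (substitution-only,
#' so positional ground truth stays exact; indels are a sequencing-stage
#' error, see [emit_reads]). Deterministic for a given seed.
#'
#' @param cfg a [sim_config].
#' @return An object of class `otn_truth`: list with `ancestor`, `sequences`
#'   (named character vector, one insert per taxon), `tree` (`phylo`),
#'   `generations` (pairwise path-length matrix), and `cfg`.
#' @export
simulate_taxa <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    tree <- cfg$tree
    if (is.null(tree)) {
      tree <- if (cfg$n_taxa >= 3L)
        ape::rtree(cfg$n_taxa, rooted = FALSE,
                   tip.label = paste0("taxon", seq_len(cfg$n_taxa)))
      else ape::stree(cfg$n_taxa, tip.label = paste0("taxon",
                                                     seq_len(cfg$n_taxa)))
      tree$edge.length <- stats::runif(nrow(tree$edge),
                                       cfg$edge_range[1], cfg$edge_range[2])
    }
    r <- cfg$per_position_rate
    exp_sub <- cfg$insert_length *
      (-expm1(max(tree$edge.length) * log1p(-r)))
    if (exp_sub > cfg$insert_length / 2)
      warning("edge(s) near substitution saturation (expected >L/2 hits)")
    anc <- sample.int(4L, cfg$insert_length, replace = TRUE) - 1L
    ntip <- length(tree$tip.label)
    root <- ntip + 1L
    seqs_at <- vector("list", ntip + tree$Nnode)
    seqs_at[[root]] <- anc
    tr <- ape::reorder.phylo(tree, "cladewise")
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      g <- tr$edge.length[e]
      p_sub <- -expm1(g * log1p(-r))
      seqs_at[[child]] <- .mutate_codes(seqs_at[[parent]], p_sub)
    }
    seqs <- vapply(seq_len(ntip), function(i) .codes_to_seq(seqs_at[[i]]),
                   "")
    names(seqs) <- tree$tip.label
    gen <- ape::cophenetic.phylo(tree)[tree$tip.label, tree$tip.label]
    structure(list(ancestor = .codes_to_seq(anc), sequences = seqs,
                   tree = tree, generations = gen, cfg = cfg),
              class = "otn_truth")
  })
}

#' @export
print.otn_truth <- function(x, ...) {
  cat(sprintf("<otn_truth> %d taxa, insert %d nt, max separation %.3g generations\n",
              length(x$sequences), x$cfg$insert_length,
              max(x$generations)))
  invisible(x)
}

# Inject at most one +/-1-base indel per homopolymer tract (run >= 3) with
# the given per-tract probability; returns list(seq, events data.frame).
.inject_homopolymer_indels <- function(s, rate) {
  if (rate <= 0) return(list(seq = s, events = NULL))
  v <- strsplit(s, NULL)[[1]]
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tract <- which(r$lengths >= 3L)
  if (!length(tract)) return(list(seq = s, events = NULL))
  hit <- tract[stats::runif(length(tract)) < rate]
  if (!length(hit)) return(list(seq = s, events = NULL))
  events <- data.frame(start = starts[hit], length = r$lengths[hit],
                       base = r$values[hit],
                       change = sample(c(-1L, 1L), length(hit),
                                       replace = TRUE))
  # apply right-to-left so earlier coordinates stay valid
  for (k in order(events$start, decreasing = TRUE)) {
    pos <- events$start[k]
    if (events$change[k] == 1L) {
      v <- append(v, events$base[k], after = pos - 1L)
    } else {
      v <- v[-pos]
    }
  }
  list(seq = paste(v, collapse = ""), events = events)
}

#' Emit reads from simulated taxa
#'
#' Per taxon, `reads_per_taxon` copies of `fwd_primer + insert +
#' revcomp(rev_primer)` are produced, homopolymer indels are injected at the
#' configured per-tract rate, and per-base error probabilities follow the
#' linear quality profile. Each taxon is written as its own sample. The
#' injected-error ledger is attached as attribute `error_ledger`.
#'
#' @param truth an `otn_truth` from [simulate_taxa].
#' @param cfg the [sim_config] (defaults to the one stored in `truth`).
#' @param dir optional directory; when given, one FASTQ per sample is
#'   written there (`<taxon>.fastq`).
#' @return An [amplicon_reads] object (samples = taxa), with attribute
#'   `error_ledger` (data frame: read id, tract start/base/length, change).
#' @export
emit_reads <- function(truth, cfg = truth$cfg, dir = NULL) {
  with_seed(cfg$seed + 1L, {
    rc <- revcomp(cfg$rev_primer)
    ids <- character(0); seqs <- character(0); samp <- character(0)
    quals <- list()
    ledger <- list()
    for (taxon in names(truth$sequences)) {
      amplicon <- paste0(cfg$fwd_primer, truth$sequences[[taxon]], rc)
      for (k in seq_len(cfg$reads_per_taxon)) {
        id <- sprintf("%s_read%03d", taxon, k)
        inj <- .inject_homopolymer_indels(amplicon,
                                          cfg$homopolymer_indel_rate)
        L <- nchar(inj$seq)
        p <- cfg$mean_error *
          (1 + cfg$error_decay * (seq_len(L) - 1L) / max(1L, L - 1L))
        p <- pmin(p, 0.75)
        ids <- c(ids, id); seqs <- c(seqs, inj$seq)
        samp <- c(samp, taxon); quals <- c(quals, list(p))
        if (!is.null(inj$events)) {
          inj$events$id <- id
          ledger[[length(ledger) + 1L]] <- inj$events
        }
      }
    }
    reads <- amplicon_reads(ids, seqs, quals, samp)
    attr(reads, "error_ledger") <- if (length(ledger))
      do.call(rbind, ledger)
    else data.frame(start = integer(0), length = integer(0),
                    base = character(0), change = integer(0),
                    id = character(0))
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (taxon in unique(samp)) {
        sel <- reads[samp == taxon]
        write_amplicons(sel, file.path(dir, paste0(taxon, ".fastq")),
                        "fastq")
      }
    }
    reads
  })
}

#' Build an end-to-end pipeline fixture with ground truth
#'
#' Bundles simulated taxa, emitted reads, and the expected outcomes (one OTN
#' pattern per taxon for error-free input; the true pairwise generation
#' matrix; the generating tree) for pipeline-level validation.
#'
#' @param cfg a small [sim_config] (intended for <= 12 taxa).
#' @param dir optional directory for FASTQ output (passed to [emit_reads]).
#' @return list with `truth`, `reads`, `expected_n_patterns`,
#'   `expected_generations`, `tree`.
#' @export
end_to_end_fixture <- function(cfg = sim_config(), dir = NULL) {
  truth <- simulate_taxa(cfg)
  reads <- emit_reads(truth, cfg, dir = dir)
  list(truth = truth, reads = reads,
       expected_n_patterns = length(unique(truth$sequences)),
       expected_generations = truth$generations,
       tree = truth$tree)
}

#' Simulate diverged OTN profile pairs and re-estimate their separation
#'
#' Constructs profile pairs under the exponential-decay character model: of
#' `n_otns` ancestral OTNs, each remains shared after `generations` of total
#' separation with probability `(1 - rate)^generations`; a mutated OTN
#' becomes a private column of one profile, so both profiles keep size
#' `n_otns`. The separation is then re-estimated from the profiles with
#' [pairwise_generations], giving a direct parameter-recovery check with
#' binomial sampling noise.
#'
#' @param n_otns number of OTN columns per profile.
#' @param generations true total separation.
#' @param rate per-generation OTN mutation probability.
#' @param reps number of independent pairs.
#' @param seed RNG seed.
#' @return data frame with columns `shared`, `estimate` and `se` (delta-
#'   method standard error of the estimate from binomial noise at the true
#'   survival probability).
#' @export
simulate_profile_pairs <- function(n_otns = 10000L, generations,
                                   rate = 0.5e-9, reps = 1L, seed = 1L) {
  q <- exp(generations * log1p(-rate))
  params <- gen_params(rate = rate)
  with_seed(seed, {
    out <- vapply(seq_len(reps), function(i) {
      keep <- stats::runif(n_otns) < q
      k <- sum(keep)
      n_priv <- n_otns - k
      a <- c(rep(1L, n_otns), rep(0L, n_priv))
      b <- c(as.integer(keep), rep(1L, n_priv))
      pairwise_generations(a, b, params)
    }, numeric(1))
    se <- sqrt(n_otns * q * (1 - q)) / (n_otns * q * abs(log1p(-rate)))
    data.frame(estimate = out, se = se, truth = generations)
  })
}
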