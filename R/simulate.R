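# Seeded simulator: a host genome carrying an annotated prophage plus a
# free (autonomous) phage, sampled as error-bearing paired-end reads with
# per-read truth labels. This is the ground-truth fixture for the pipeline's
# central contract: with the prophage masked, prophage- and free-phage reads
# survive subtraction while host reads are removed.
#
# The sequences are i.i.d. uniform over ACGT — no GC skew, no repeats — so
# the discriminating experiments are sharp: host and phage share homology
# only by chance, and the simulator checks the free phage against the host
# backbone for shared seed-length words, regenerating on excess collision.
# Reads are substitution-only (no indels), matching the mapper's ungapped
# alignment model.

#' Simulation configuration
#'
#' Defaults describe the reference scenario used throughout the package:
#' a 200 kb host with a 30 kb integrated prophage, a 40 kb free phage, and
#' 10 000 error-bearing read pairs of which 20% derive from the free phage
#' and 10% from the prophage locus (the remainder is host backbone).
#'
#' @param host_length Host genome length in bp.
#' @param prophage_length Length of the integrated prophage; it replaces a
#'   host window (the emitted host record length stays `host_length`).
#' @param free_phage_length Length of the autonomous phage genome.
#' @param prophage_insert_pos 1-based start of the prophage inside the host.
#' @param n_pairs Number of mate pairs to sample.
#' @param read_length Read length in bp.
#' @param insert_size_mean,insert_size_sd Gaussian insert-size model, bp.
#' @param error_rate Per-base substitution probability.
#' @param phage_read_fraction Fraction of pairs drawn from the free phage.
#' @param prophage_read_fraction Fraction drawn from the prophage locus.
#' @param seed Integer seed; all simulate operations are deterministic in it.
#' @param collision_tolerance Maximum number of seed-length (15-mer) words
#'   the free phage may share with the host backbone before it is
#'   regenerated.
#' @return A `sim_config` object.
#' @export
sim_config <- function(host_length = 200000L, prophage_length = 30000L,
                       free_phage_length = 40000L,
                       prophage_insert_pos = 100001L,
                       n_pairs = 10000L, read_length = 150L,
                       insert_size_mean = 400L, insert_size_sd = 40L,
                       error_rate = 0.01, phage_read_fraction = 0.2,
                       prophage_read_fraction = 0.1, seed = 42L,
                       collision_tolerance = 25L) {
  cfg <- list(host_length = as.integer(host_length),
              prophage_length = as.integer(prophage_length),
              free_phage_length = as.integer(free_phage_length),
              prophage_insert_pos = as.integer(prophage_insert_pos),
              n_pairs = as.integer(n_pairs),
              read_length = as.integer(read_length),
              insert_size_mean = as.numeric(insert_size_mean),
              insert_size_sd = as.numeric(insert_size_sd),
              error_rate = as.numeric(error_rate),
              phage_read_fraction = as.numeric(phage_read_fraction),
              prophage_read_fraction = as.numeric(prophage_read_fraction),
              seed = as.integer(seed),
              collision_tolerance = as.integer(collision_tolerance))
  if (cfg$phage_read_fraction + cfg$prophage_read_fraction > 1) {
    abort("origin fractions must sum to at most 1")
  }
  if (cfg$error_rate < 0 || cfg$error_rate >= 1) {
    abort("error_rate must be in [0, 1)")
  }
  if (cfg$prophage_insert_pos < 1L ||
      cfg$prophage_insert_pos + cfg$prophage_length - 1L > cfg$host_length) {
    abort("prophage insert position out of range: ",
          cfg$prophage_insert_pos, "..",
          cfg$prophage_insert_pos + cfg$prophage_length - 1L,
          " does not fit in a ", cfg$host_length, " bp host")
  }
  if (cfg$read_length > cfg$insert_size_mean - 2 * cfg$insert_size_sd) {
    warning("read_length exceeds insert_size_mean - 2*insert_size_sd; ",
            "mates will frequently overlap", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

viral_products <- c("phage integrase",
                    "phage tail fiber protein",
                    "phage major capsid protein",
                    "phage terminase large subunit",
                    "phage portal protein",
                    "prophage CP4-like repressor",
                    "phage holin",
                    "viral recombinase",
                    "phage baseplate assembly protein",
                    "viral DNA packaging protein")

host_products <- c("hypothetical protein",
                   "DNA polymerase III subunit alpha",
                   "50S ribosomal protein L2",
                   "ABC transporter permease",
                   "two-component sensor histidine kinase")

#' Simulate the host (with annotated prophage) and the free phage
#'
#' The host record carries the prophage as a contiguous insert replacing a
#' window at `prophage_insert_pos`; coding-region features tile the whole
#' prophage span with products containing "phage"/"viral" (so the default
#' [mask_policy()] selects them, and inter-feature gaps are kept well below
#' a read length so no unmasked prophage window can anchor an alignment).
#' A few non-viral host CDSs are annotated outside the prophage. Host
#' backbone, prophage and free phage are generated independently at uniform
#' base composition from the seed; the free phage is regenerated if it
#' shares more than `collision_tolerance` 15-mers with the host backbone.
#'
#' @param cfg A [sim_config()].
#' @return List: `host` (list of `records`, `features`), `phage`
#'   (records data.frame), `prophage_start`, `prophage_end`, `cfg`.
#' @export
simulate_genomes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  backbone <- random_dna(cfg$host_length)
  prophage <- random_dna(cfg$prophage_length)
  bk_words <- unique(kmers_of(backbone, 15L))
  phage_seq <- NULL
  for (try in 1:5) {
    cand <- random_dna(cfg$free_phage_length)
    shared <- sum(unique(kmers_of(cand, 15L)) %in% bk_words)
    if (shared <= cfg$collision_tolerance) {
      phage_seq <- cand
      break
    }
  }
  if (is.null(phage_seq)) {
    abort("could not generate a free phage with at most ",
          cfg$collision_tolerance, " shared 15-mers after 5 attempts")
  }
  ps <- cfg$prophage_insert_pos
  pe <- ps + cfg$prophage_length - 1L
  host_seq <- paste0(substr(backbone, 1L, ps - 1L), prophage,
                     substr(backbone, pe + 1L, cfg$host_length))

  # prophage CDS tiling: ~900 bp genes with 80 bp gaps, last gene extended
  # to the prophage end so every internal gap stays far below a read length
  gene_len <- 900L
  gap <- 80L
  starts <- seq(ps, pe, by = gene_len + gap)
  ends <- pmin(starts + gene_len - 1L, pe)
  ends[length(ends)] <- pe  # last gene runs to the prophage end
  n_genes <- length(starts)
  prods <- viral_products[(seq_len(n_genes) - 1L) %% length(viral_products) + 1L]
  strands <- rep(c("+", "-"), length.out = n_genes)
  quals <- lapply(seq_len(n_genes), function(i) {
    list(locus_tag = sprintf("SIMPP_%03d", i), product = prods[i])
  })
  pro_feats <- features_frame(seq_id = rep("simhost01", n_genes),
                              start = starts, end = ends, strand = strands,
                              kind = rep("CDS", n_genes),
                              feature_id = sprintf("SIMPP_%03d",
                                                   seq_len(n_genes)),
                              qualifiers = quals)

  # a few annotated (non-viral) host genes on the backbone
  host_gene_starts <- as.integer(round(seq(2000,
                                           max(2001, ps - 3000),
                                           length.out = 5)))
  hq <- lapply(seq_along(host_gene_starts), function(i) {
    list(locus_tag = sprintf("SIMHG_%03d", i),
         product = host_products[(i - 1L) %% length(host_products) + 1L])
  })
  host_feats <- features_frame(seq_id = rep("simhost01", 5L),
                               start = host_gene_starts,
                               end = host_gene_starts + 999L,
                               strand = rep("+", 5L),
                               kind = rep("CDS", 5L),
                               feature_id = sprintf("SIMHG_%03d", 1:5),
                               qualifiers = hq)

  host <- list(records = data.frame(id = "simhost01",
                                    description = "simulated host genome with integrated prophage",
                                    seq = host_seq, stringsAsFactors = FALSE),
               features = rbind(host_feats, pro_feats))
  phage <- data.frame(id = "simphage01",
                      description = "simulated autonomous phage genome",
                      seq = phage_seq, stringsAsFactors = FALSE)
  list(host = host, phage = phage, prophage_start = ps, prophage_end = pe,
       cfg = cfg)
}

.add_substitutions <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  idx <- which(nerr > 0L)
  raw_bases <- vapply(DNA_BASES, charToRaw, raw(1))
  for (i in idx) {
    r <- charToRaw(seqs[i])
    pos <- sample.int(lens[i], nerr[i])
    for (p in pos) {
      cur <- r[p]
      alt <- raw_bases[raw_bases != cur]
      r[p] <- alt[sample.int(length(alt), 1L)]
    }
    seqs[i] <- rawToChar(r)
  }
  seqs
}

#' Simulate truth-labelled paired-end reads
#'
#' Samples `n_pairs` mate pairs from the simulated genomes according to the
#' origin fractions. Host-origin inserts are drawn wholly from the backbone
#' (never straddling the prophage window), prophage-origin inserts wholly
#' from inside the prophage, free-phage inserts from the phage genome —
#' keeping the truth labels unambiguous. Insert sizes are Gaussian, clamped
#' to `[2*read_length, region length]`; each pair's forward/reverse mate
#' assignment is random; substitution errors are i.i.d. at `error_rate`;
#' base qualities are constant.
#'
#' @param genomes Output of [simulate_genomes()].
#' @param cfg The same [sim_config()] (defaults to `genomes$cfg`).
#' @return List: `reads` (data.frame `id`, `seq`, `qual`, `mate`, pairwise
#'   interleaved) and `truth` (data.frame `read_id`, `origin`,
#'   `source_start`, `source_strand`).
#' @export
simulate_reads <- function(genomes, cfg = genomes$cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  n <- cfg$n_pairs
  rl <- cfg$read_length
  ps <- genomes$prophage_start
  pe <- genomes$prophage_end
  host_seq <- genomes$host$records$seq
  phage_seq <- genomes$phage$seq
  hl <- nchar(host_seq)

  f_host <- 1 - cfg$phage_read_fraction - cfg$prophage_read_fraction
  origins <- sample(c("host", "prophage", "free_phage"), n, replace = TRUE,
                    prob = c(f_host, cfg$prophage_read_fraction,
                             cfg$phage_read_fraction))

  # candidate regions: (source, start, end); host backbone is two segments
  regions <- list(host_left = c(1L, ps - 1L),
                  host_right = c(pe + 1L, hl),
                  prophage = c(ps, pe),
                  phage = c(1L, nchar(phage_seq)))
  reg_len <- vapply(regions, function(r) r[2] - r[1] + 1L, integer(1))
  min_needed <- 2L * rl
  usable <- reg_len >= min_needed
  if (!usable[["prophage"]] || !usable[["phage"]] ||
      !(usable[["host_left"]] || usable[["host_right"]])) {
    abort("a source region is shorter than twice the read length; ",
          "cannot place inserts")
  }

  region_of <- character(n)
  region_of[origins == "prophage"] <- "prophage"
  region_of[origins == "free_phage"] <- "phage"
  hosts <- which(origins == "host")
  w <- pmax(0, reg_len[c("host_left", "host_right")] - min_needed + 1)
  region_of[hosts] <- sample(c("host_left", "host_right"), length(hosts),
                             replace = TRUE, prob = w)

  ins <- as.integer(round(stats::rnorm(n, cfg$insert_size_mean,
                                       cfg$insert_size_sd)))
  ins <- pmax(min_needed, pmin(ins, reg_len[region_of]))
  rstart <- vapply(regions, `[`, integer(1), 1L)[region_of]
  rend <- vapply(regions, `[`, integer(1), 2L)[region_of]
  span <- rend - rstart - ins + 2L  # number of valid insert starts
  st <- rstart + as.integer(floor(stats::runif(n) * span))

  src <- ifelse(region_of == "phage", "phage", "host")
  fwd_ins <- character(n)
  for (s in c("host", "phage")) {
    i <- which(src == s)
    if (!length(i)) next
    source_seq <- if (s == "host") host_seq else phage_seq
    fwd_ins[i] <- substring(source_seq, st[i], st[i] + ins[i] - 1L)
  }
  r_fwd <- substr(fwd_ins, 1L, rl)                    # + strand read
  r_rev <- revcomp(substring(fwd_ins, ins - rl + 1L)) # - strand read
  start_fwd <- st
  start_rev <- st + ins - rl

  swap <- stats::runif(n) < 0.5  # which physical read is reported as /1
  mate1_seq <- ifelse(swap, r_rev, r_fwd)
  mate2_seq <- ifelse(swap, r_fwd, r_rev)
  mate1_start <- ifelse(swap, start_rev, start_fwd)
  mate2_start <- ifelse(swap, start_fwd, start_rev)
  mate1_strand <- ifelse(swap, "-", "+")
  mate2_strand <- ifelse(swap, "+", "-")

  mate1_seq <- .add_substitutions(mate1_seq, cfg$error_rate)
  mate2_seq <- .add_substitutions(mate2_seq, cfg$error_rate)

  base <- sprintf("sim_%06d", seq_len(n))
  id1 <- paste0(base, "/1")
  id2 <- paste0(base, "/2")
  qual <- strrep("I", rl)
  reads <- data.frame(
    id = as.vector(rbind(id1, id2)),
    seq = as.vector(rbind(mate1_seq, mate2_seq)),
    qual = qual,
    mate = rep(c(1L, 2L), n),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    read_id = as.vector(rbind(id1, id2)),
    origin = rep(origins, each = 2L),
    source_start = as.vector(rbind(mate1_start, mate2_start)),
    source_strand = as.vector(rbind(mate1_strand, mate2_strand)),
    stringsAsFactors = FALSE)
  list(reads = reads, truth = truth)
}

#' Write the full simulated fixture to disk
#'
#' Emits the annotated host as a GenBank flat file, the free phage as
#' FASTA, the read pairs as two FASTQ files, and the truth table as TSV.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `genomes`, `sim` (reads + truth) and
#'   `paths` (named character vector).
#' @export
simulate_fixture <- function(cfg = sim_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genomes <- simulate_genomes(cfg)
  sim <- simulate_reads(genomes, cfg)
  paths <- c(host = file.path(out_dir, "host.gbk"),
             phage = file.path(out_dir, "phage.fasta"),
             reads1 = file.path(out_dir, "reads_R1.fastq"),
             reads2 = file.path(out_dir, "reads_R2.fastq"),
             truth = file.path(out_dir, "truth.tsv"))
  write_genbank(genomes$host$records, genomes$host$features, paths[["host"]])
  ss <- Biostrings::DNAStringSet(genomes$phage$seq)
  names(ss) <- paste(genomes$phage$id, genomes$phage$description)
  Biostrings::writeXStringSet(ss, paths[["phage"]], width = 80L)
  write_fastq(sim$reads[sim$reads$mate == 1L, ], paths[["reads1"]])
  write_fastq(sim$reads[sim$reads$mate == 2L, ], paths[["reads2"]])
  write_tsv(sim$truth, paths[["truth"]])
  invisible(list(genomes = genomes, sim = sim, paths = paths))
}

#' Score a pipeline run against the simulator's truth labels
#'
#' @param truth Truth data.frame from [simulate_reads()] (or the TSV read
#'   back in).
#' @param retained_ids Character vector of retained read ids.
#' @return List with `host_removal_rate`, `phage_retention_rate`,
#'   `prophage_retention_rate` and a `counts` data.frame (per-origin totals,
#'   retained and removed counts).
#' @export
score_run <- function(truth, retained_ids) {
  unknown <- setdiff(retained_ids, truth$read_id)
  if (length(unknown)) {
    abort("retained read id not present in the truth table: ", unknown[1])
  }
  retained <- truth$read_id %in% retained_ids
  origins <- c("host", "prophage", "free_phage")
  counts <- data.frame(origin = origins,
                       total = vapply(origins, function(o) {
                         sum(truth$origin == o)
                       }, integer(1)),
                       retained = vapply(origins, function(o) {
                         sum(retained & truth$origin == o)
                       }, integer(1)))
  counts$removed <- counts$total - counts$retained
  rate <- function(o, what) {
    tot <- counts$total[counts$origin == o]
    if (tot == 0) return(NA_real_)
    counts[[what]][counts$origin == o] / tot
  }
  list(host_removal_rate = rate("host", "removed"),
       phage_retention_rate = rate("free_phage", "retained"),
       prophage_retention_rate = rate("prophage", "retained"),
       counts = counts)
}
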