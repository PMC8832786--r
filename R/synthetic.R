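#' Configuration for the synthetic RenSeq assembly generator
#'
#' Bundles every knob of the synthetic contig generator with validation. The
#' defaults emulate the composition reported for a SMRT-RenSeq survey of a
#' diploid Triticeae NLR complement: roughly a fifth of loci partial, a
#' quarter pseudogenised, ~7% integrated-domain fusions, ~11% of NLR-bearing
#' contigs carrying a tandem pair, a few percent near-duplicate contigs at 97%
#' identity, and a strong 4VL-to-group-7 homoeology discordance.
#'
#' @param seed integer master seed; identical configs give byte-identical
#'   outputs.
#' @param n_contigs total number of contigs to emit (NLR-bearing plus
#'   NLR-free background; near-duplicates come on top).
#' @param contig_length_range numeric length-2 vector, min/max contig length
#'   in bp; loci (with flanks) that cannot fit raise an error.
#' @param n_loci number of planted NLR loci.
#' @param pseudogene_rate,partial_rate,id_fusion_rate,tandem_rate,
#'   near_duplicate_rate,discordant_group_fraction,transcript_rate fractions
#'   in `[0, 1]` (see Details).
#' @param duplicate_identity percent identity of near-duplicate contigs to
#'   their source.
#' @param transcript_error_rate per-base substitution rate in emitted
#'   transcripts.
#' @param intron_rate fraction of complete, non-pseudogene loci carrying a
#'   single intron (codon-length, stop-free, GT..AG).
#' @param flank_range bp of random background on each side of a planted locus.
#' @return a validated list of class `synthetic_config`.
#' @details `pseudogene_rate` plants an in-frame TAA stop or a 1-bp
#'   frameshift inside the motif span; `partial_rate` drops the LRR block
#'   (CC-NB loci) or both head and LRR (NB-only); `id_fusion_rate` appends an
#'   integrated-domain motif at the N or C side of complete loci;
#'   `discordant_group_fraction` sends that fraction of 4VL-arm loci to
#'   homoeologous-group-7 chromosomes in the reference hit table.
#' @export
synthetic_config <- function(seed = 42,
                             n_contigs = 250,
                             contig_length_range = c(6000, 24000),
                             n_loci = 200,
                             pseudogene_rate = 0.27,
                             partial_rate = 0.19,
                             id_fusion_rate = 0.067,
                             tandem_rate = 0.11,
                             near_duplicate_rate = 0.035,
                             duplicate_identity = 97,
                             discordant_group_fraction = 0.9,
                             transcript_rate = 0.12,
                             transcript_error_rate = 0.002,
                             intron_rate = 0.3,
                             flank_range = c(800, 2500)) {
  cfg <- list(
    seed = assert_count(seed, "seed", min = 0L),
    n_contigs = assert_count(n_contigs, "n_contigs"),
    contig_length_range = contig_length_range,
    n_loci = assert_count(n_loci, "n_loci"),
    pseudogene_rate = assert_fraction(pseudogene_rate, "pseudogene_rate"),
    partial_rate = assert_fraction(partial_rate, "partial_rate"),
    id_fusion_rate = assert_fraction(id_fusion_rate, "id_fusion_rate"),
    tandem_rate = assert_fraction(tandem_rate, "tandem_rate"),
    near_duplicate_rate = assert_fraction(near_duplicate_rate, "near_duplicate_rate"),
    duplicate_identity = duplicate_identity,
    discordant_group_fraction = assert_fraction(discordant_group_fraction,
                                                "discordant_group_fraction"),
    transcript_rate = assert_fraction(transcript_rate, "transcript_rate"),
    transcript_error_rate = assert_fraction(transcript_error_rate,
                                            "transcript_error_rate"),
    intron_rate = assert_fraction(intron_rate, "intron_rate"),
    flank_range = flank_range
  )
  if (length(contig_length_range) != 2L || contig_length_range[1] <= 0 ||
      diff(contig_length_range) < 0) {
    stop("contig_length_range must be c(min, max) with min <= max", call. = FALSE)
  }
  if (length(flank_range) != 2L || flank_range[1] < 0 ||
      diff(flank_range) < 0) {
    stop("flank_range must be c(min, max) with 0 <= min <= max", call. = FALSE)
  }
  if (duplicate_identity <= 50 || duplicate_identity > 100) {
    stop("duplicate_identity must be in (50, 100]", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

# Build one planted locus. Returns the strand-oriented DNA (5'->3' of the
# gene), the protein, spliced CDS, motif chain, and intron offsets within the
# oriented DNA. Uses the current RNG stream.
#' @noRd
.build_locus <- function(library, kind, pseudo, id_row, id_terminal, intron) {
  cc <- library[library$category == "CC", ]
  nb <- library[library$category == "NB", ]
  lrr <- library[library$category == "LRR", ]
  # p_loop motif first within the NB block, then the NB-ARC start motif
  nb <- nb[order(!nb$p_loop, !nb$nb_start), ]
  blocks <- switch(kind,
    complete = list(cc, nb, lrr),
    partial_cn = list(cc, nb),
    partial_n = list(nb)
  )
  if (!is.null(id_row)) {
    blocks <- if (id_terminal == "N") c(list(id_row), blocks) else c(blocks, list(id_row))
  }
  motifs <- dplyr::bind_rows(blocks)
  # amino-acid scaffold: M + (linker + motif)* + linker
  linkers <- vapply(seq_len(nrow(motifs) + 1L),
                    function(i) random_aa(sample(8:30, 1L)), character(1))
  aa <- "M"
  aa_block_end <- integer(nrow(motifs)) # aa index where each motif ends
  for (i in seq_len(nrow(motifs))) {
    aa <- paste0(aa, linkers[i], motifs$consensus[i])
    aa_block_end[i] <- nchar(aa)
  }
  aa <- paste0(aa, linkers[nrow(motifs) + 1L])
  cds <- paste0(reverse_translate(aa), "TGA")

  # disruption point: first residue of the linker following the middle motif
  mid <- max(1L, floor(nrow(motifs) / 2))
  disrupt_aa <- aa_block_end[mid] + 2L

  dna <- cds
  if (pseudo == "stop") {
    nt <- (disrupt_aa - 1L) * 3L + 1L
    substr(dna, nt, nt + 2L) <- "TAA"
    cds <- dna
  } else if (pseudo == "frameshift") {
    nt <- (disrupt_aa - 1L) * 3L + 2L
    dna <- paste0(substr(dna, 1L, nt - 1L), substr(dna, nt + 1L, nchar(dna)))
    cds <- dna
  }

  intron_off <- NA_integer_; intron_len <- NA_integer_
  if (intron && kind == "complete" && pseudo == "none") {
    # between the NB and LRR blocks (codon boundary)
    nb_end <- aa_block_end[nrow(cc) + nrow(nb) + if (!is.null(id_row) && id_terminal == "N") 1L else 0L]
    at_aa <- nb_end + 3L
    off <- at_aa * 3L # 0-based nt offset of the insertion point
    intron_len <- 3L * sample(40:100, 1L)
    body <- vapply(seq_len(intron_len / 3L - 2L), function(i) {
      sample(setdiff(unlist(.codon_table), c("TAA", "TAG", "TGA")), 1L)
    }, character(1))
    intron <- paste0("GTA", paste(body, collapse = ""), "CAG")
    dna <- paste0(substr(dna, 1L, off), intron, substr(dna, off + 1L, nchar(dna)))
    intron_off <- off
  }

  list(dna = dna, protein = aa, cds = cds, chain = motifs$motif_id,
       intron_offset = intron_off, intron_length = intron_len)
}

#' Generate a synthetic contig set with planted ground truth
#'
#' Plants motif-grammar NLR loci (complete, partial, pseudogene, tandem pairs
#' and integrated-domain fusions) in random-background contigs (i.i.d. bases,
#' 45% GC) and returns the contigs together with a truth table, near-duplicate
#' bookkeeping and a homolog protein database. Coordinates are 0-based
#' half-open on the forward strand.
#'
#' @param config a [synthetic_config()].
#' @param library a motif library ([generate_motif_library()]).
#' @return a list of class `synthetic_set`:
#'   * `contigs`: tibble (`contig_id`, `sequence`) incl. background and
#'     near-duplicate contigs;
#'   * `truth`: tibble, one row per planted locus (`locus_id`, `contig_id`,
#'     `start`, `end`, `strand`, `true_completeness`, `true_class`,
#'     `id_domain`, `id_terminal`, `true_group`, `physical_arm`, `protein`,
#'     `cds`, `intron_offset`, `intron_length`);
#'   * `duplicates`: tibble (`contig_id`, `source_contig_id`, `identity`);
#'   * `homologs`: tibble (`protein_id`, `locus_id`, `protein`) for complete,
#'     non-pseudogene loci.
#' @export
generate_contig_set <- function(config, library) {
  stopifnot(inherits(config, "synthetic_config"))
  library <- validate_motif_library(library)
  n <- config$n_loci
  withr::with_seed(config$seed, {
    partial <- stats::runif(n) < config$partial_rate
    pseudo <- ifelse(stats::runif(n) < config$pseudogene_rate,
                     sample(c("stop", "frameshift"), n, replace = TRUE), "none")
    kind <- ifelse(!partial, "complete",
                   sample(c("partial_cn", "partial_n"), n, replace = TRUE))
    fused <- !partial & stats::runif(n) < config$id_fusion_rate
    id_lib <- library[library$category == "ID", ]
    if (any(fused) && nrow(id_lib) == 0L) {
      stop("id_fusion_rate > 0 needs ID motifs in the library", call. = FALSE)
    }
    has_intron <- kind == "complete" & pseudo == "none" &
      stats::runif(n) < config$intron_rate
    strand <- sample(c("+", "-"), n, replace = TRUE)
    true_group <- sample(1:7, n, replace = TRUE)
    physical_arm <- paste0(true_group, "V", sample(c("S", "L"), n, replace = TRUE))

    loci <- vector("list", n)
    for (i in seq_len(n)) {
      id_row <- NULL; id_term <- NA_character_
      if (fused[i]) {
        id_row <- id_lib[sample.int(nrow(id_lib), 1L), ]
        id_term <- sample(c("N", "C"), 1L)
      }
      loci[[i]] <- c(.build_locus(library, kind[i], pseudo[i], id_row, id_term,
                                  has_intron[i]),
                     list(id_domain = if (fused[i]) id_row$motif_id else NA_character_,
                          id_terminal = id_term))
    }

    # assign loci to contigs; tandem pairs share one contig
    assign <- integer(n); contig_k <- 0L; i <- 1L
    while (i <= n) {
      contig_k <- contig_k + 1L
      if (i < n && stats::runif(1) < config$tandem_rate) {
        assign[c(i, i + 1L)] <- contig_k; i <- i + 2L
      } else {
        assign[i] <- contig_k; i <- i + 1L
      }
    }
    min_len <- config$contig_length_range[1]
    max_len <- config$contig_length_range[2]

    contig_seq <- character(contig_k)
    truth <- vector("list", n)
    for (k in seq_len(contig_k)) {
      idx <- which(assign == k)
      cid <- paste0("Contig_", k)
      lf <- sample(config$flank_range[1]:config$flank_range[2], 1L)
      seq <- random_dna(lf)
      for (j in seq_along(idx)) {
        i <- idx[j]
        l <- loci[[i]]
        oriented <- l$dna
        placed <- if (strand[i] == "+") oriented else revcomp(oriented)
        start <- nchar(seq)
        seq <- paste0(seq, placed)
        truth[[i]] <- tibble::tibble(
          locus_id = paste0(cid, "_nlr_", j),
          contig_id = cid,
          start = start, end = nchar(seq), strand = strand[i],
          true_completeness = paste0(
            if (kind[i] == "complete") "complete" else "partial",
            if (pseudo[i] != "none") "_pseudogene" else ""),
          true_class = classify_motif_chain(l$chain, library),
          id_domain = l$id_domain, id_terminal = l$id_terminal,
          true_group = true_group[i], physical_arm = physical_arm[i],
          protein = l$protein, cds = l$cds,
          intron_offset = l$intron_offset, intron_length = l$intron_length
        )
        if (j < length(idx)) seq <- paste0(seq, random_dna(sample(4000:6000, 1L)))
      }
      rf <- sample(config$flank_range[1]:config$flank_range[2], 1L)
      seq <- paste0(seq, random_dna(rf))
      if (nchar(seq) < min_len) seq <- paste0(seq, random_dna(min_len - nchar(seq)))
      if (nchar(seq) > max_len) {
        stop("planted loci on ", cid, " (", nchar(seq),
             " bp) do not fit contig_length_range", call. = FALSE)
      }
      contig_seq[k] <- seq
    }
    truth <- dplyr::bind_rows(truth)

    n_bg <- config$n_contigs - contig_k
    if (n_bg < 0L) {
      stop("n_contigs (", config$n_contigs, ") smaller than the ", contig_k,
           " contigs needed for n_loci", call. = FALSE)
    }
    bg <- tibble::tibble(
      contig_id = if (n_bg > 0L) paste0("Contig_", contig_k + seq_len(n_bg)) else character(0),
      sequence = vapply(seq_len(n_bg),
                        function(i) random_dna(sample(min_len:max_len, 1L)),
                        character(1))
    )

    contigs <- dplyr::bind_rows(
      tibble::tibble(contig_id = paste0("Contig_", seq_len(contig_k)),
                     sequence = contig_seq),
      bg
    )

    # near-duplicate copies of NLR-bearing contigs (substitutions only, so
    # greedy longest-first dedup retains the original on the length tie)
    dup_src <- which(stats::runif(contig_k) < config$near_duplicate_rate)
    dups <- tibble::tibble(contig_id = character(0),
                           source_contig_id = character(0), identity = numeric(0))
    for (k in dup_src) {
      src <- contig_seq[k]
      nmut <- round(nchar(src) * (100 - config$duplicate_identity) / 100)
      pos <- sample.int(nchar(src), nmut)
      chars <- strsplit(src, "")[[1]]
      chars[pos] <- vapply(chars[pos],
                           function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                           character(1))
      dup_id <- paste0("Contig_", k, "_dup")
      contigs <- dplyr::bind_rows(contigs,
        tibble::tibble(contig_id = dup_id, sequence = paste(chars, collapse = "")))
      dups <- dplyr::bind_rows(dups,
        tibble::tibble(contig_id = dup_id, source_contig_id = paste0("Contig_", k),
                       identity = config$duplicate_identity))
    }

    homolog_rows <- truth[truth$true_completeness == "complete", ]
    homologs <- tibble::tibble(
      protein_id = paste0("hom_", homolog_rows$locus_id),
      locus_id = homolog_rows$locus_id,
      protein = homolog_rows$protein
    )

    structure(list(contigs = contigs, truth = truth, duplicates = dups,
                   homologs = homologs, config = config, library = library),
              class = "synthetic_set")
  })
}

#' Generate a reference best-hit table with homoeologous-group structure
#'
#' Emulates a BLAST best-hit table of planted loci against related Triticeae
#' genomes. Each locus receives one best hit per genome on chromosome
#' `<group><genome letter>`; a configurable fraction of loci physically on the
#' 4VL arm hit homoeologous-group-7 chromosomes in every genome, emulating the
#' ancestral 4L/7S translocation discordance.
#'
#' @param truth truth table from [generate_contig_set()].
#' @param genomes genome labels among `"AABBDD"`, `"AA"`, `"DD"`, `"HH"`.
#' @param discordant_group_fraction fraction of 4VL loci rerouted to group 7.
#' @param seed integer seed.
#' @return tibble (`query_id`, `genome`, `chromosome`, `identity`,
#'   `coverage`, `bitscore`).
#' @export
generate_reference_hits <- function(truth,
                                    genomes = c("AABBDD", "HH", "DD"),
                                    discordant_group_fraction = 0.9,
                                    seed = 1) {
  if (nrow(truth) == 0L) stop("truth table is empty", call. = FALSE)
  assert_fraction(discordant_group_fraction, "discordant_group_fraction")
  letters_by_genome <- list(AABBDD = c("A", "B", "D"), AA = "A", DD = "D", HH = "H")
  unknown <- setdiff(genomes, names(letters_by_genome))
  if (length(unknown)) stop("unknown genome label: ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  withr::with_seed(seed, {
    on_4vl <- truth$physical_arm == "4VL"
    discordant <- on_4vl & stats::runif(nrow(truth)) < discordant_group_fraction
    group_eff <- ifelse(discordant, 7L, truth$true_group)
    purrr::map_dfr(genomes, function(g) {
      lets <- letters_by_genome[[g]]
      tibble::tibble(
        query_id = truth$locus_id,
        genome = g,
        chromosome = paste0(group_eff, sample(lets, nrow(truth), replace = TRUE)),
        identity = round(stats::runif(nrow(truth), 80, 99), 1),
        coverage = round(stats::runif(nrow(truth), 60, 99), 1),
        bitscore = round(stats::runif(nrow(truth), 500, 3000), 1)
      )
    })
  })
}

#' Generate transcripts for planted loci
#'
#' Emits the spliced coding sequence of a sample of complete, non-pseudogene
#' loci with per-base substitution errors, emulating a full-length transcript
#' set. Optionally shifts the donor site of intron-bearing loci to plant a
#' splice-pattern mismatch.
#'
#' @param truth,contigs from [generate_contig_set()].
#' @param transcript_rate fraction of eligible loci transcribed.
#' @param transcript_error_rate per-base substitution rate.
#' @param seed integer seed.
#' @param junction_shift_bp if > 0, transcripts of intron-bearing loci retain
#'   this many genomic bases past the true donor site.
#' @return tibble (`transcript_id`, `locus_id`, `sequence`).
#' @export
generate_transcripts <- function(truth, contigs, transcript_rate = 0.12,
                                 transcript_error_rate = 0.002, seed = 1,
                                 junction_shift_bp = 0) {
  assert_fraction(transcript_rate, "transcript_rate")
  assert_fraction(transcript_error_rate, "transcript_error_rate")
  eligible <- truth[truth$true_completeness == "complete", ]
  withr::with_seed(seed, {
    keep <- eligible[stats::runif(nrow(eligible)) < transcript_rate, ]
    if (nrow(keep) == 0L) {
      return(tibble::tibble(transcript_id = character(0),
                            locus_id = character(0), sequence = character(0)))
    }
    seqs <- vapply(seq_len(nrow(keep)), function(i) {
      row <- keep[i, ]
      ctg <- contigs$sequence[contigs$contig_id == row$contig_id]
      oriented <- substr(ctg, row$start + 1L, row$end)
      if (row$strand == "-") oriented <- revcomp(oriented)
      if (!is.na(row$intron_offset)) {
        donor <- row$intron_offset + junction_shift_bp
        tx <- paste0(substr(oriented, 1L, donor),
                     substr(oriented, row$intron_offset + row$intron_length + 1L,
                            nchar(oriented)))
      } else {
        tx <- oriented
      }
      if (transcript_error_rate > 0) {
        chars <- strsplit(tx, "")[[1]]
        mut <- which(stats::runif(length(chars)) < transcript_error_rate)
        chars[mut] <- vapply(chars[mut],
                             function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                             character(1))
        tx <- paste(chars, collapse = "")
      }
      tx
    }, character(1))
    tibble::tibble(
      transcript_id = paste0("tx_", seq_len(nrow(keep))),
      locus_id = keep$locus_id,
      sequence = seqs
    )
  })
}

#' Simulate every input the pipeline consumes
#'
#' Convenience wrapper: contig set, reference hit table, physical marker
#' table (from the planted truth) and transcripts, all from one config.
#'
#' @param config a [synthetic_config()].
#' @param library optional motif library; a default 3/8/4 CC/NB/LRR library
#'   (plus 3 ID motifs) is generated from the config seed when omitted.
#' @return a `synthetic_set` list with additional elements `hits`,
#'   `markers` and `transcripts`.
#' @export
simulate_renseq <- function(config = synthetic_config(), library = NULL) {
  if (is.null(library)) {
    library <- generate_motif_library(config$seed, n_cc = 3, n_nb = 8, n_lrr = 4)
  }
  sim <- generate_contig_set(config, library)
  sim$hits <- generate_reference_hits(
    sim$truth, discordant_group_fraction = config$discordant_group_fraction,
    seed = config$seed + 1L)
  sim$markers <- tibble::tibble(
    marker_id = sim$truth$locus_id,
    status = ifelse(sim$truth$true_completeness == "complete",
                    "Complete NLR", "Partial or pseudogene"),
    physical_arm = sim$truth$physical_arm
  )
  sim$transcripts <- generate_transcripts(
    sim$truth, sim$contigs, transcript_rate = config$transcript_rate,
    transcript_error_rate = config$transcript_error_rate,
    seed = config$seed + 2L)
  sim
}

#' Write a synthetic set to an output directory
#'
#' Contigs and transcripts as FASTA, tables as TSV — the same plain-text
#' formats the pipeline reads back.
#'
#' @param sim a `synthetic_set` (see [simulate_renseq()]).
#' @param out_dir directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_synthetic <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(stats::setNames(sim$contigs$sequence, sim$contigs$contig_id),
              file.path(out_dir, "contigs.fasta"))
  readr::write_tsv(sim$truth, file.path(out_dir, "planted_truth.tsv"))
  readr::write_tsv(sim$duplicates, file.path(out_dir, "near_duplicates.tsv"))
  write_fasta(stats::setNames(sim$homologs$protein, sim$homologs$protein_id),
              file.path(out_dir, "homolog_proteins.fasta"))
  if (!is.null(sim$hits)) readr::write_tsv(sim$hits, file.path(out_dir, "reference_hits.tsv"))
  if (!is.null(sim$markers)) readr::write_tsv(sim$markers, file.path(out_dir, "physical_markers.tsv"))
  if (!is.null(sim$transcripts)) {
    write_fasta(stats::setNames(sim$transcripts$sequence, sim$transcripts$transcript_id),
                file.path(out_dir, "transcripts.fasta"))
  }
  invisible(out_dir)
}
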