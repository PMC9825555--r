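# Deterministic synthetic-data generator: mock genomes with implanted
# gene clusters copied from a mock PUL database, plus internally consistent
# per-tool annotation tables, pairwise-hit tables and curated mapping
# tables, so the whole pipeline runs end to end with no external data.
#
# Protein sequences are synthetic strings and bit scores are fabricated
# (base score + Gaussian jitter) consistently with the implant provenance:
# the toolkit consumes precomputed hits, so fixtures emulate the hit tables
# an aligner would produce, not the alignment itself.

default_compositions <- function() {
  list(
    c("CAZyme", "TC"),
    c("CAZyme", "Other", "TC", "CAZyme"),
    c("TC", "CAZyme", "Other", "Other", "CAZyme"),
    c("CAZyme", "TF", "Other", "CAZyme", "STP"),
    c("STP", "CAZyme", "Other", "TC")
  )
}

default_substrates <- function() {
  c("starch", "xylan", "pectin", "mucin", "mannan", "cellulose",
    "beta-glucan", "arabinan", "galactan", "chitin", "levan", "inulin",
    "fucoidan", "laminarin", "alginate", "pullulan", "dextran",
    "arabinogalactan", "rhamnogalacturonan", "glycogen")
}

#' Fixture generation parameters
#'
#' Defines a self-contained synthetic study: a mock PUL database with
#' known substrates, mock genomes whose contigs are mostly `Other` genes,
#' and `n_implanted_cgcs` clusters implanted as copies of randomly chosen
#' PULs. Noise knobs degrade the evidence: `drop_hit_prob` removes pairwise
#' hits, `bitscore_jitter_sd` perturbs bit scores (bits), `mislabel_prob`
#' drops a signature gene's annotation (the gene becomes `Other`).
#'
#' @param seed RNG seed; with the seed fixed the emitted bundle is
#'   byte-identical across runs.
#' @param n_genomes,contigs_per_genome,genes_per_contig genome shape;
#'   `genes_per_contig` counts background (non-implant) genes per contig.
#' @param n_implanted_cgcs number of implanted clusters, spread evenly over
#'   contigs and separated by background runs longer than the default
#'   insertion gap so implants never merge.
#' @param n_puls size of the mock PUL database.
#' @param implant_composition list of signature-class sequences used as PUL
#'   gene layouts; every sequence must contain a CAZyme and must begin and
#'   end with a signature gene (truth spans equal implant spans).
#' @param pul_substrates substrate vocabulary, recycled over PULs.
#' @param noise list with `drop_hit_prob`, `bitscore_jitter_sd`,
#'   `mislabel_prob`.
#' @return validated spec list for [make_fixture()].
#' @export
fixture_spec <- function(seed = 1,
                         n_genomes = 6,
                         contigs_per_genome = 2,
                         genes_per_contig = 25,
                         n_implanted_cgcs = 60,
                         n_puls = 20,
                         implant_composition = default_compositions(),
                         pul_substrates = default_substrates(),
                         noise = list(drop_hit_prob = 0,
                                      bitscore_jitter_sd = 5,
                                      mislabel_prob = 0)) {
  noise <- modifyList(list(drop_hit_prob = 0, bitscore_jitter_sd = 5,
                           mislabel_prob = 0), noise)
  stopifnot(
    n_genomes >= 1, contigs_per_genome >= 1, n_puls >= 1,
    n_implanted_cgcs >= 0,
    noise$drop_hit_prob >= 0, noise$drop_hit_prob <= 1,
    noise$mislabel_prob >= 0, noise$mislabel_prob <= 1,
    noise$bitscore_jitter_sd >= 0,
    length(pul_substrates) >= 1
  )
  for (comp in implant_composition) {
    if (!any(comp == "CAZyme")) {
      stop("every implant composition must contain a CAZyme", call. = FALSE)
    }
    if (comp[1] == "Other" || comp[length(comp)] == "Other") {
      stop("implant compositions must start and end with a signature gene",
           call. = FALSE)
    }
    if (!all(comp %in% GENE_CLASSES)) {
      stop("unknown gene class in implant composition", call. = FALSE)
    }
  }
  n_contigs <- n_genomes * contigs_per_genome
  per_contig <- ceiling(n_implanted_cgcs / n_contigs)
  if (genes_per_contig < 3 * (per_contig + 1)) {
    stop("genes_per_contig too small to separate ", per_contig,
         " implants per contig by >2 background genes", call. = FALSE)
  }
  list(seed = as.integer(seed), n_genomes = n_genomes,
       contigs_per_genome = contigs_per_genome,
       genes_per_contig = genes_per_contig,
       n_implanted_cgcs = n_implanted_cgcs, n_puls = n_puls,
       implant_composition = implant_composition,
       pul_substrates = pul_substrates, noise = noise)
}

random_protein <- function(n = 200) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# split f background genes into k+1 runs, each of length >= 3 when
# f >= 3 * (k + 1); remainder goes to the first runs
split_runs <- function(f, k) {
  base <- f %/% (k + 1)
  runs <- rep(base, k + 1)
  extra <- f - base * (k + 1)
  if (extra > 0) runs[seq_len(extra)] <- runs[seq_len(extra)] + 1L
  runs
}

#' Generate a synthetic input bundle
#'
#' Writes a complete fixture directory: `genes.gff` (all genomes, with a
#' `genome` attribute per feature), `proteins.faa` and `pul_proteins.faa`
#' (synthetic sequences), `cazyme_hits.tsv` (per-tool CAZyme calls; implant
#' CAZymes are reported by two tools, background decoys by one tool only so
#' the consensus rule removes them), `signature_labels.tsv` (TC/TF/STP
#' calls), `hits.tsv` (12-column tabular pairwise hits of genome proteins
#' vs PUL proteins), `pul_substrate.tsv`, `subfamily_substrate.tsv`,
#' `pul_proteins.tsv`, and `truth.tsv` recording every implanted cluster's
#' span, source PUL and substrate.
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the file `paths` and the `truth` tibble.
#' @export
make_fixture <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(spec$seed, make_fixture_impl(spec, dir))
}

make_fixture_impl <- function(spec, dir) {
  families <- c("GH5", "GH13", "GH43", "GH2", "GH3", "GH130", "GH10",
                "GH26", "GH31", "PL1", "CE1", "GT2")

  ## --- mock PUL database -------------------------------------------------
  puls <- vector("list", spec$n_puls)
  subfam_rows <- list()
  sub_counter <- 0L
  for (i in seq_len(spec$n_puls)) {
    pid <- sprintf("PUL%03d", i)
    comp <- spec$implant_composition[[
      sample.int(length(spec$implant_composition), 1)]]
    substrate <- spec$pul_substrates[((i - 1) %% length(spec$pul_substrates)) + 1]
    prot <- sprintf("%s_P%02d", pid, seq_along(comp))
    subfam <- rep(NA_character_, length(comp))
    fam <- rep(NA_character_, length(comp))
    for (j in which(comp == "CAZyme")) {
      sub_counter <- sub_counter + 1L
      fam[j] <- sample(families, 1)
      subfam[j] <- sprintf("%s_e%d", fam[j], sub_counter)
      subfam_rows[[length(subfam_rows) + 1L]] <- tibble::tibble(
        family = fam[j], ecami_subfamily = subfam[j],
        ec_numbers = "3.2.1.-", substrate = substrate
      )
    }
    puls[[i]] <- list(pul_id = pid, substrate = substrate, composition = comp,
                      proteins = prot, families = fam, subfamilies = subfam)
  }
  # decoy subfamilies: present in the table but with no curated substrate
  for (d in 1:4) {
    sub_counter <- sub_counter + 1L
    subfam_rows[[length(subfam_rows) + 1L]] <- tibble::tibble(
      family = families[d], ecami_subfamily = sprintf("%s_e%d", families[d], sub_counter),
      ec_numbers = "", substrate = NA_character_
    )
  }
  subfam_map <- dplyr::bind_rows(subfam_rows)
  pul_substrate <- tibble::tibble(
    pul_id = vapply(puls, `[[`, "", "pul_id"),
    substrate = vapply(puls, `[[`, "", "substrate")
  )
  pul_proteins <- dplyr::bind_rows(lapply(puls, function(p) {
    tibble::tibble(pul_id = p$pul_id, protein_id = p$proteins,
                   gene_class = p$composition)
  }))

  ## --- genomes with implants --------------------------------------------
  contigs <- expand.grid(
    contig = sprintf("c%d", seq_len(spec$contigs_per_genome)),
    genome = sprintf("G%03d", seq_len(spec$n_genomes)),
    stringsAsFactors = FALSE
  )[, c("genome", "contig")]
  n_contigs <- nrow(contigs)
  implants_per_contig <- rep(spec$n_implanted_cgcs %/% n_contigs, n_contigs)
  extra <- spec$n_implanted_cgcs %% n_contigs
  if (extra > 0) {
    implants_per_contig[seq_len(extra)] <- implants_per_contig[seq_len(extra)] + 1L
  }
  implant_sources <- if (spec$n_implanted_cgcs > 0) {
    sample.int(spec$n_puls, spec$n_implanted_cgcs, replace = TRUE)
  } else {
    integer()
  }

  genes <- list()
  caz_hits <- list()
  sig_labels <- list()
  hit_rows <- list()
  truth <- list()
  implant_idx <- 0L

  for (ci in seq_len(n_contigs)) {
    genome <- contigs$genome[ci]
    contig <- contigs$contig[ci]
    k <- implants_per_contig[ci]
    runs <- split_runs(spec$genes_per_contig, k)
    slots <- list()
    for (r in seq_len(k + 1)) {
      slots[[length(slots) + 1L]] <- list(kind = "bg", n = runs[r])
      if (r <= k) {
        implant_idx <- implant_idx + 1L
        slots[[length(slots) + 1L]] <- list(kind = "implant",
                                            src = implant_sources[implant_idx])
      }
    }

    pos <- 0L
    for (slot in slots) {
      if (slot$kind == "bg") {
        for (b in seq_len(slot$n)) {
          pos <- pos + 1L
          gid <- sprintf("%s_%s_g%04d", genome, contig, pos)
          genes[[length(genes) + 1L]] <- tibble::tibble(
            gene_id = gid, genome_id = genome, contig_id = contig,
            start = 1L + (pos - 1L) * 1500L, end = (pos - 1L) * 1500L + 1200L,
            strand = "+", protein_id = gid
          )
          u <- runif(1)
          if (u < 0.10) {
            # single-tool CAZyme decoy: removed by the >=2-tool consensus
            caz_hits[[length(caz_hits) + 1L]] <- tibble::tibble(
              protein_id = gid, tool = "hmm",
              family = sample(families, 1), score = 1e-12
            )
          } else if (u < 0.15 && b == 4 && slot$n >= 7) {
            # isolated transporter deep inside a background run: a lone
            # non-CAZyme signature gene that must not seed a cluster
            sig_labels[[length(sig_labels) + 1L]] <- tibble::tibble(
              protein_id = gid, gene_class = "TC", detail = "decoy transporter"
            )
          }
        }
      } else {
        p <- puls[[slot$src]]
        start_ord <- pos # 0-based ordinal of first implant gene
        for (j in seq_along(p$composition)) {
          pos <- pos + 1L
          gid <- sprintf("%s_%s_g%04d", genome, contig, pos)
          genes[[length(genes) + 1L]] <- tibble::tibble(
            gene_id = gid, genome_id = genome, contig_id = contig,
            start = 1L + (pos - 1L) * 1500L, end = (pos - 1L) * 1500L + 1200L,
            strand = "+", protein_id = gid
          )
          cls <- p$composition[j]
          mislabelled <- runif(1) < spec$noise$mislabel_prob
          if (cls == "CAZyme" && !mislabelled) {
            caz_hits[[length(caz_hits) + 1L]] <- tibble::tibble(
              protein_id = gid,
              tool = c("hmm", "kmer"),
              family = c(p$families[j], p$subfamilies[j]),
              score = c(1e-25, 0.85)
            )
          } else if (cls %in% c("TC", "TF", "STP") && !mislabelled) {
            sig_labels[[length(sig_labels) + 1L]] <- tibble::tibble(
              protein_id = gid, gene_class = cls, detail = "implant"
            )
          }
          # fabricated alignment hit to the source PUL counterpart
          if (runif(1) >= spec$noise$drop_hit_prob) {
            bits <- max(50, 180 + rnorm(1, sd = spec$noise$bitscore_jitter_sd))
            hit_rows[[length(hit_rows) + 1L]] <- tibble::tibble(
              query_protein = gid, subject_protein = p$proteins[j],
              identity = round(runif(1, 80, 99), 1), bit_score = round(bits, 1),
              e_value = 1e-50
            )
          }
          # weak decoy hit against a different PUL; a single pair can never
          # satisfy the CAZyme-plus-other eligibility rule
          if (j == 1 && spec$n_puls > 1) {
            other <- puls[[(slot$src %% spec$n_puls) + 1L]]
            hit_rows[[length(hit_rows) + 1L]] <- tibble::tibble(
              query_protein = gid, subject_protein = other$proteins[1],
              identity = round(runif(1, 25, 35), 1), bit_score = 40,
              e_value = 1e-5
            )
          }
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          genome_id = genome, contig_id = contig,
          start_ordinal = start_ord,
          end_ordinal = pos - 1L,
          pul_id = p$pul_id, substrate = p$substrate
        )
      }
    }
  }

  genes <- assign_ordinals(dplyr::bind_rows(genes))
  caz_hits <- if (length(caz_hits)) dplyr::bind_rows(caz_hits) else
    tibble::tibble(protein_id = character(), tool = character(),
                   family = character(), score = double())
  sig_labels <- if (length(sig_labels)) dplyr::bind_rows(sig_labels) else
    tibble::tibble(protein_id = character(), gene_class = character(),
                   detail = character())
  hit_tbl <- if (length(hit_rows)) dplyr::bind_rows(hit_rows) else
    tibble::tibble(query_protein = character(), subject_protein = character(),
                   identity = double(), bit_score = double(), e_value = double())
  truth <- if (length(truth)) dplyr::bind_rows(truth) else
    tibble::tibble(genome_id = character(), contig_id = character(),
                   start_ordinal = integer(), end_ordinal = integer(),
                   pul_id = character(), substrate = character())

  ## --- write the bundle ---------------------------------------------------
  paths <- list(
    gff = file.path(dir, "genes.gff"),
    proteins = file.path(dir, "proteins.faa"),
    pul_proteins_fasta = file.path(dir, "pul_proteins.faa"),
    cazyme_hits = file.path(dir, "cazyme_hits.tsv"),
    signature_labels = file.path(dir, "signature_labels.tsv"),
    hits = file.path(dir, "hits.tsv"),
    pul_substrate = file.path(dir, "pul_substrate.tsv"),
    subfamily_substrate = file.path(dir, "subfamily_substrate.tsv"),
    pul_proteins = file.path(dir, "pul_proteins.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_gff(genes, paths$gff)

  seqs <- Biostrings::AAStringSet(vapply(genes$protein_id, function(x)
    random_protein(), ""))
  names(seqs) <- genes$protein_id
  Biostrings::writeXStringSet(seqs, paths$proteins, width = 60)
  pseqs <- Biostrings::AAStringSet(vapply(pul_proteins$protein_id, function(x)
    random_protein(), ""))
  names(pseqs) <- pul_proteins$protein_id
  Biostrings::writeXStringSet(pseqs, paths$pul_proteins_fasta, width = 60)

  readr::write_tsv(caz_hits, paths$cazyme_hits, progress = FALSE)
  readr::write_tsv(sig_labels, paths$signature_labels, progress = FALSE)
  write_hits_outfmt6(hit_tbl, paths$hits)
  readr::write_tsv(pul_substrate, paths$pul_substrate, progress = FALSE)
  readr::write_tsv(
    tibble::tibble(
      family = subfam_map$family, ecami_subfamily = subfam_map$ecami_subfamily,
      ec_numbers = subfam_map$ec_numbers, substrate = subfam_map$substrate
    ),
    paths$subfamily_substrate, progress = FALSE, na = ""
  )
  readr::write_tsv(pul_proteins, paths$pul_proteins, progress = FALSE)
  readr::write_tsv(truth, paths$truth, progress = FALSE)

  invisible(list(paths = paths, truth = truth))
}

# serialize hits as 12-column BLAST tabular (outfmt 6), no header
write_hits_outfmt6 <- function(hits, path) {
  lines <- sprintf(
    "%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.1f",
    hits$query_protein, hits$subject_protein, hits$identity,
    200L, 10L, 1L, 1L, 200L, 1L, 200L,
    hits$e_value, hits$bit_score
  )
  writeLines(lines, path)
  invisible(path)
}

#' Measure implant recovery on a fixture
#'
#' Matches every implanted cluster (truth row) to a detected cluster with
#' the identical ordinal span on the same contig, then checks whether the
#' given substrate assignment reproduces the implant's source substrate
#' (normalized comparison).
#'
#' @param truth the `truth` tibble from [make_fixture()].
#' @param cgc_genes detected clusters ([find_cgcs()] output).
#' @param assignments assignment tibble (`cgc_id`, `substrate`).
#' @return a list: `n_implants`, `n_detected` (span recovered exactly),
#'   `n_recovered` (detected and substrate correct), `detection_rate` and
#'   `recovery_rate` (fractions of implants).
#' @export
fixture_recovery <- function(truth, cgc_genes, assignments) {
  spans <- cgc_summary(cgc_genes)
  key <- function(g, c, s, e) paste(g, c, s, e, sep = "\r")
  span_key <- key(spans$genome_id, spans$contig_id,
                  spans$start_ordinal, spans$end_ordinal)
  truth_key <- key(truth$genome_id, truth$contig_id,
                   truth$start_ordinal, truth$end_ordinal)
  hit <- match(truth_key, span_key)
  detected <- !is.na(hit)
  cgc_ids <- spans$cgc_id[hit]
  assigned <- assignments$substrate[match(cgc_ids, assignments$cgc_id)]
  recovered <- detected & !is.na(assigned) &
    norm_substrate(assigned) == norm_substrate(truth$substrate)
  n <- nrow(truth)
  list(
    n_implants = n,
    n_detected = sum(detected),
    n_recovered = sum(recovered),
    detection_rate = if (n > 0) sum(detected) / n else NA_real_,
    recovery_rate = if (n > 0) sum(recovered) / n else NA_real_
  )
}
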