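# Seeded synthetic-data generators: a complete toy phase-change study
# (reference miRNAs, genome with planted hairpin/decoy loci, per-library
# small-RNA reads with isomiR structure and planted fold changes, target
# transcripts, qPCR Ct tables) with a ground-truth manifest. All generators
# are pure functions of (parameters, seed).

plant_family_pool <- c(
  "miR156", "miR159", "miR160", "miR164", "miR165", "miR166", "miR167",
  "miR168", "miR169", "miR171", "miR172", "miR319", "miR390", "miR393",
  "miR394", "miR395", "miR396", "miR398", "miR403", "miR408", "miR472",
  "miR482", "miR858", "miR2118"
)

#' Generate a reference set of planted mature miRNAs
#'
#' Each family receives a random 21-nt mature sequence at moderately high GC
#' (so the corresponding genomic hairpins fold stably) and one or two
#' miRBase-style accessions; the second accession, when present, carries one
#' substitution so family grouping and ambiguity handling are exercised.
#'
#' @param n_families Number of families to plant.
#' @param seed Integer seed.
#' @param mature_len Mature length (nt).
#' @return Tibble in the shape of [read_mirbase_fasta()] output.
#' @export
make_reference_mirnas <- function(n_families = 20L, seed = 1L,
                                  mature_len = 21L) {
  if (n_families > length(plant_family_pool)) {
    abort("n_families exceeds the built-in family pool")
  }
  with_seed(seed + 101L, {
    fams <- plant_family_pool[seq_len(n_families)]
    rows <- purrr::map_dfr(seq_along(fams), function(i) {
      mat <- random_dna(1, mature_len, gc = 0.55)
      out <- tibble(
        accession = paste0("gma-", fams[i], "a"),
        species_code = "gma", family = fams[i], arm = NA_character_,
        kind = "mature", sequence = mat
      )
      if (i %% 2 == 0) {  # half the families get a 1-mismatch second member
        pos <- sample(5:(mature_len - 4), 1)
        ch <- strsplit(mat, "")[[1]]
        ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
        out <- bind_rows(out, mutate(out[1, ],
          accession = paste0("ath-", fams[i], "b"),
          species_code = "ath", sequence = paste(ch, collapse = "")
        ))
      }
      out
    })
    rows
  })
}

# Stem-loop cassette embedding a mature arm in a near-perfect hairpin:
# outer stem (12 bp), 3-nt bulge, 21-bp mature/star duplex, 6-nt loop,
# 2-nt bulge. Valid by construction against the hairpin criteria.
hairpin_cassette <- function(mature) {
  outer <- random_dna(1, 12, gc = 0.6)
  b1 <- "AAA"
  loop <- random_dna(1, 6, gc = 0.2)
  b2 <- "AA"
  seq <- paste0(outer, b1, mature, loop, revcomp(mature), b2, revcomp(outer))
  mature_offset <- nchar(outer) + nchar(b1)  # 0-based offset of mature
  list(sequence = seq, mature_offset = mature_offset)
}

#' Generate a toy genome with planted hairpin loci and decoys
#'
#' Valid loci embed each family's mature arm inside a stem-loop cassette
#' (mature/star duplex with 2-nt 3' overhang symmetry, bulged outer stem);
#' decoy loci embed the bare mature sequence in unstructured low-GC context.
#' One family is planted as a tandem cluster of three copies ~500 nt apart,
#' and roughly a third of loci go on the minus strand.
#'
#' @param mirnas Reference tibble from [make_reference_mirnas()] (the first
#'   accession per family is planted).
#' @param n_contigs,contig_len Genome dimensions (contig_len >= 1000).
#' @param n_decoys Number of decoy loci.
#' @param seed Integer seed.
#' @param gc Background GC fraction.
#' @return List with `genome` (named character vector) and `loci` (tibble:
#'   `contig`, `start0`, `end0`, `strand`, `family`, `mirna_id`,
#'   `is_valid_hairpin`, `in_cluster`). Coordinates span the full cassette.
#' @export
make_genome <- function(mirnas, n_contigs = 10L, contig_len = 50000L,
                        n_decoys = 20L, seed = 1L, gc = 0.38) {
  if (contig_len < 1000) abort("contig_len must be >= 1000")
  with_seed(seed + 202L, {
    primary <- mirnas %>%
      group_by(.data$family) %>%
      dplyr::slice(1) %>%
      ungroup()
    contigs <- random_dna(n_contigs, contig_len, gc = gc)
    names(contigs) <- sprintf("Contig%02d", seq_len(n_contigs))
    loci <- list()
    occupied <- purrr::map(seq_len(n_contigs), ~matrix(numeric(0), ncol = 2))

    place <- function(cassette, contig_idx = NULL, pos = NULL) {
      len <- nchar(cassette)
      if (len + 400 > contig_len) abort("cassette longer than contig")
      for (try in 1:200) {
        ci <- if (is.null(contig_idx)) sample(n_contigs, 1) else contig_idx
        p <- if (is.null(pos)) sample(200:(contig_len - len - 200), 1) else pos
        occ <- occupied[[ci]]
        clear <- nrow(occ) == 0 ||
          all(p + len + 300 < occ[, 1] | p > occ[, 2] + 300)
        if (clear) {
          occupied[[ci]] <<- rbind(occ, c(p, p + len))
          return(list(ci = ci, p = p))
        }
      }
      abort("could not place cassette without overlap")
    }

    for (i in seq_len(nrow(primary))) {
      fam <- primary$family[i]
      mat <- primary$sequence[i]
      n_copies <- if (i == 1) 3L else 1L  # first family: tandem cluster
      anchor <- NULL
      for (k in seq_len(n_copies)) {
        cas <- hairpin_cassette(mat)
        strand <- if (n_copies == 1 && runif(1) < 0.35) "-" else "+"
        ins <- if (strand == "+") cas$sequence else revcomp(cas$sequence)
        if (k == 1) {
          at <- place(ins)
          anchor <- at
        } else {
          at <- place(ins, contig_idx = anchor$ci,
                      pos = anchor$p + (k - 1) * (nchar(ins) + 500))
        }
        substr(contigs[at$ci], at$p + 1, at$p + nchar(ins)) <- ins
        loci[[length(loci) + 1]] <- tibble(
          contig = names(contigs)[at$ci],
          start0 = at$p, end0 = at$p + nchar(ins), strand = strand,
          family = fam, mirna_id = primary$accession[i],
          is_valid_hairpin = TRUE, in_cluster = n_copies > 1
        )
      }
    }
    # decoys: mature sequence in unstructured low-GC context
    decoy_fams <- rep(primary$family, length.out = n_decoys)
    for (d in seq_len(n_decoys)) {
      fam <- decoy_fams[d]
      mat <- primary$sequence[primary$family == fam]
      ins <- paste0(random_dna(1, 40, gc = 0.2), mat,
                    random_dna(1, 40, gc = 0.2))
      at <- place(ins)
      substr(contigs[at$ci], at$p + 1, at$p + nchar(ins)) <- ins
      loci[[length(loci) + 1]] <- tibble(
        contig = names(contigs)[at$ci],
        start0 = at$p, end0 = at$p + nchar(ins), strand = "+",
        family = fam, mirna_id = primary$accession[primary$family == fam],
        is_valid_hairpin = FALSE, in_cluster = FALSE
      )
    }
    list(genome = contigs, loci = bind_rows(loci))
  })
}

#' Default toy study design
#'
#' Four maturity states with four libraries each (rejuvenated and mature
#' in vitro shoots, juvenile seedlings, mature-tree leaves).
#'
#' @return Design tibble (`library_id`, `sample_group`).
#' @export
default_design <- function() {
  groups <- c(rep("REV", 4), rep("IVM", 4), rep("JUV", 4), rep("MAT", 4))
  tibble(
    library_id = paste0(groups, "_", stats::ave(seq_along(groups), groups,
                                                FUN = seq_along)),
    sample_group = groups
  )
}

#' Plant per-family expression truth
#'
#' A subset of families is differentially expressed: their designated "up"
#' group has `fold_change` times the baseline mean; all other families are
#' flat across groups.
#'
#' @param mirnas Reference tibble.
#' @param n_de Number of DE families.
#' @param fold_change Planted fold change.
#' @param base_mean Baseline expected count per library.
#' @param seed Integer seed.
#' @return Tibble: `family`, `mature_sequence`, `is_de`, `up_group`,
#'   `fold_change`, and one `mean_<group>` column per group.
#' @export
make_expression_truth <- function(mirnas, n_de = 10L, fold_change = 4,
                                  base_mean = 200, seed = 1L) {
  groups <- c("REV", "IVM", "JUV", "MAT")
  with_seed(seed + 303L, {
    primary <- mirnas %>%
      group_by(.data$family) %>%
      dplyr::slice(1) %>%
      ungroup()
    fams <- primary$family
    de <- fams[seq_len(min(n_de, length(fams)))]
    # balance up-groups so library-size composition shifts stay comparable
    up <- sample(rep_len(groups, length(de)))
    truth <- tibble(
      family = fams,
      mature_sequence = primary$sequence,
      is_de = fams %in% de,
      up_group = NA_character_,
      fold_change = 1
    )
    truth$up_group[truth$is_de] <- up
    truth$fold_change[truth$is_de] <- fold_change
    base <- exp(rnorm(length(fams), log(base_mean), 0.4))
    for (g in groups) {
      truth[[paste0("mean_", g)]] <-
        base * ifelse(truth$is_de & truth$up_group == g, fold_change, 1)
    }
    truth
  })
}

# IsomiR variant catalogue for one mature sequence: canonical, length
# variants (+/- 1-2 nt at either end) and single-substitution variants,
# with the configured class probabilities.
isomir_catalogue <- function(mature, p_canonical = 0.6, p_length = 0.3,
                             p_subst = 0.1) {
  L <- nchar(mature)
  len_vars <- c(
    substr(mature, 2, L), substr(mature, 3, L),
    substr(mature, 1, L - 1), substr(mature, 1, L - 2),
    paste0(mature, "A"), paste0("T", mature)
  )
  sub_vars <- vapply(c(4L, 12L), function(pos) {
    ch <- strsplit(mature, "")[[1]]
    ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
    paste(ch, collapse = "")
  }, character(1))
  tibble(
    sequence = c(mature, len_vars, sub_vars),
    prob = c(p_canonical, rep(p_length / length(len_vars), length(len_vars)),
             rep(p_subst / length(sub_vars), length(sub_vars)))
  )
}

#' Simulate per-library small-RNA reads
#'
#' Per library, family counts are drawn negative-binomially around the group
#' means in `truth`; reads sample isomiR variants (60% canonical, 30% length
#' variants within +/-2 nt, 10% single substitutions), get the adapter
#' appended and uniform qualities. A background fraction of random low-copy
#' reads is added.
#'
#' @param truth Expression truth from [make_expression_truth()].
#' @param design Design tibble.
#' @param seed Integer seed.
#' @param depth Approximate reads per library attributable to planted
#'   families (scales the family means to a common depth).
#' @param dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param background_fraction Fraction of additional random reads.
#' @param adapter Adapter appended to each read.
#' @return Tibble with `library_id`, `read_id`, `sequence`, `quality` for all
#'   libraries stacked.
#' @export
make_reads <- function(truth, design, seed = 1L, depth = 20000L,
                       dispersion = 0.2,
                       background_fraction = 0.1,
                       adapter = "TGGAATTCTCGGGTGCCAAGG") {
  with_seed(seed + 404L, {
    cats <- purrr::map(seq_len(nrow(truth)), function(i) {
      isomir_catalogue(truth$mature_sequence[i])
    })
    out <- purrr::map_dfr(seq_len(nrow(design)), function(li) {
      lib <- design$library_id[li]
      grp <- design$sample_group[li]
      mu <- truth[[paste0("mean_", grp)]]
      mu <- mu / sum(mu) * depth
      counts <- rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      seqs <- purrr::map2(seq_along(counts), counts, function(i, n) {
        if (n == 0) return(character())
        sample(cats[[i]]$sequence, n, replace = TRUE, prob = cats[[i]]$prob)
      })
      seqs <- unlist(seqs)
      n_bg <- rnbinom(1, mu = background_fraction * depth, size = 10)
      bg <- random_dna(max(n_bg, 0), 22, gc = 0.45)
      if (length(bg) > 0) bg <- substr(bg, 1, sample(18:22, length(bg), TRUE))
      all_seqs <- c(seqs, bg)
      ord <- sample(length(all_seqs))
      all_seqs <- all_seqs[ord]
      reads <- paste0(all_seqs, adapter)
      tibble(
        library_id = lib,
        read_id = sprintf("%s_r%06d", lib, seq_along(reads)),
        sequence = reads,
        quality = strrep("I", nchar(reads))
      )
    })
    out
  })
}

#' Simulate transcripts with planted miRNA target sites
#'
#' Each planted family gets one transcript carrying a complementary site of
#' designed expectation cycling through 0, 2, 3.5 and 6 (the last is a
#' planted negative above the reporting cut-off). Designed expectations are
#' derived from the penalty arithmetic: substitutions at chosen positions
#' contribute 2 per seed mismatch, 1 per non-seed mismatch and 0.5 per
#' non-seed G:U wobble.
#'
#' @param truth Expression truth tibble.
#' @param seed Integer seed.
#' @param utr_len Length of random sequence either side of the planted site.
#' @return List with `transcripts` (named character vector) and `sites`
#'   (tibble: `family`, `mirna_sequence`, `transcript_id`, `site_start`,
#'   `site_end` 1-based inclusive, `expectation_designed`).
#' @export
make_transcripts <- function(truth, seed = 1L, utr_len = 150L) {
  with_seed(seed + 505L, {
    designs <- rep(c(0, 2, 3.5, 6), length.out = nrow(truth))
    rows <- list()
    transcripts <- character()
    for (i in seq_len(nrow(truth))) {
      mat <- truth$mature_sequence[i]
      site <- design_site(mat, designs[i])
      left <- random_dna(1, utr_len, gc = 0.45)
      right <- random_dna(1, utr_len, gc = 0.45)
      tx <- paste0(left, site$site, right)
      id <- sprintf("TX_%s", truth$family[i])
      transcripts[[id]] <- tx
      rows[[i]] <- tibble(
        family = truth$family[i], mirna_sequence = mat, transcript_id = id,
        site_start = utr_len + 1L,
        site_end = utr_len + nchar(site$site),
        expectation_designed = site$expectation
      )
    }
    list(transcripts = transcripts, sites = bind_rows(rows))
  })
}

# Mutate a perfect complementary site to a designed expectation. Returns the
# site sequence (5'->3' on the transcript) and the achieved design value.
design_site <- function(mature, target_expectation,
                        seed_start = 2L, seed_end = 13L) {
  L <- nchar(mature)
  q <- strsplit(revcomp(mature), "")[[1]]  # perfect site in Q-space
  site <- q
  achieved <- 0
  # helper: mutate site column k to a clean mismatch (never wobble/match)
  clean_mismatch <- function(k) {
    wob <- switch(site[k], C = "T", A = "G", NA_character_)
    choices <- setdiff(c("A", "C", "G", "T"), c(site[k], wob))
    sample(choices, 1)
  }
  remaining <- target_expectation
  # one seed mismatch contributes 2
  while (remaining >= 2) {
    p <- sample(seq(seed_start + 1L, seed_end - 1L), 1)  # miRNA position
    k <- L + 1L - p
    if (site[k] == q[k]) {
      site[k] <- clean_mismatch(k)
      achieved <- achieved + 2
      remaining <- remaining - 2
    }
  }
  # one non-seed mismatch contributes 1
  while (remaining >= 1) {
    p <- sample(seq(seed_end + 2L, L - 1L), 1)
    k <- L + 1L - p
    if (site[k] == q[k]) {
      site[k] <- clean_mismatch(k)
      achieved <- achieved + 1
      remaining <- remaining - 1
    }
  }
  # a non-seed wobble contributes 0.5 (needs a C or A column outside the seed)
  if (remaining >= 0.5) {
    ks <- which(site %in% c("C", "A"))
    ks <- ks[(L + 1L - ks) > seed_end & (L + 1L - ks) > 1 & site[ks] == q[ks]]
    if (length(ks) > 0) {
      k <- if (length(ks) == 1) ks else sample(ks, 1)
      site[k] <- if (site[k] == "C") "T" else "G"
      achieved <- achieved + 0.5
    }
  }
  list(site = paste(site, collapse = ""), expectation = achieved)
}

#' Simulate a qPCR Ct table
#'
#' Two effect-free reference genes (actin, cyclophilin) plus target genes
#' with per-group Ct shifts (a ddCt of -2 cycles yields a relative
#' quantity of 4 after the qPCR stage). Three technical replicates per
#' sample.
#'
#' @param effects Named list mapping target gene -> named numeric vector of
#'   per-group Ct shifts (cycles; negative = higher expression).
#' @param design Design tibble (one qPCR sample per library).
#' @param seed Integer seed.
#' @param baseline_target,baseline_refs Baseline Ct values.
#' @param sample_sd,replicate_sd Biological and technical noise (cycles).
#' @return Tibble: `sample_id`, `sample_group`, `gene_id`, `replicate`, `ct`.
#' @export
make_ct_table <- function(effects, design, seed = 1L,
                          baseline_target = 25, baseline_refs = c(18, 20),
                          sample_sd = 0.15, replicate_sd = 0.05) {
  with_seed(seed + 606L, {
    ref_genes <- c(actin = baseline_refs[1], cyclophilin = baseline_refs[2])
    rows <- list()
    for (si in seq_len(nrow(design))) {
      sample_id <- paste0("S_", design$library_id[si])
      grp <- design$sample_group[si]
      genes <- c(
        purrr::imap(effects, function(eff, gene) {
          baseline_target + (if (grp %in% names(eff)) eff[[grp]] else 0)
        }),
        as.list(ref_genes)
      )
      for (gene in names(genes)) {
        mu <- genes[[gene]] + rnorm(1, 0, sample_sd)
        rows[[length(rows) + 1]] <- tibble(
          sample_id = sample_id, sample_group = grp, gene_id = gene,
          replicate = 1:3, ct = mu + rnorm(3, 0, replicate_sd)
        )
      }
    }
    bind_rows(rows)
  })
}

#' Simulate a complete toy study with ground truth
#'
#' Bundles every generator into one seeded call and optionally writes all
#' inputs (design TSV, per-library FASTQ, reference miRNA FASTA, genome
#' FASTA, transcript FASTA, Ct CSV) plus a YAML truth manifest to a
#' directory.
#'
#' @param seed Integer seed driving every generator.
#' @param preset `"default"` (20 families, 10 contigs x 50 kb, ~20k reads
#'   per library) or `"tiny"` (8 families, 4 contigs x 8 kb, ~3k reads).
#' @param out_dir Optional output directory.
#' @param n_de Number of DE families (defaults by preset).
#' @param fold_change Planted fold change between the up group and the rest.
#' @return List of class `phasemir_study`: `design`, `reference`, `genome`,
#'   `loci`, `reads`, `transcripts`, `target_sites`, `ct_table`, `truth`,
#'   `params`.
#' @export
simulate_study <- function(seed = 1L, preset = c("default", "tiny"),
                           out_dir = NULL, n_de = NULL, fold_change = 4) {
  preset <- match.arg(preset)
  p <- if (preset == "default") {
    list(n_families = 20L, n_contigs = 10L, contig_len = 50000L,
         n_decoys = 20L, depth = 20000L, n_de = 10L)
  } else {
    list(n_families = 8L, n_contigs = 4L, contig_len = 8000L,
         n_decoys = 8L, depth = 3000L, n_de = 4L)
  }
  if (!is.null(n_de)) p$n_de <- n_de
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  design <- default_design()
  reference <- make_reference_mirnas(p$n_families, seed)
  gen <- make_genome(reference, p$n_contigs, p$contig_len, p$n_decoys, seed)
  truth <- make_expression_truth(reference, p$n_de, fold_change, seed = seed)
  reads <- make_reads(truth, design, seed, depth = p$depth, adapter = adapter)
  tx <- make_transcripts(truth, seed)
  effects <- list(pre_target = c(MAT = 0, JUV = -2, REV = -1.5, IVM = -0.5))
  ct <- make_ct_table(effects, design, seed)
  study <- structure(list(
    design = design, reference = reference,
    genome = gen$genome, loci = gen$loci,
    reads = reads, transcripts = tx$transcripts, target_sites = tx$sites,
    ct_table = ct, truth = truth,
    params = c(p, list(seed = seed, preset = preset,
                       fold_change = fold_change, adapter = adapter,
                       qpcr_effects = effects))
  ), class = "phasemir_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' @export
print.phasemir_study <- function(x, ...) {
  cat("<phasemir_study> seed ", x$params$seed, ", preset ", x$params$preset,
      ": ", nrow(x$design), " libraries, ",
      n_distinct(x$truth$family), " planted families (",
      sum(x$truth$is_de), " DE), ",
      length(x$genome), " contigs, ", nrow(x$loci), " planted loci\n",
      sep = "")
  invisible(x)
}

#' Write a simulated study to disk
#'
#' @param study A `phasemir_study`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fq_dir <- file.path(out_dir, "reads")
  dir.create(fq_dir, showWarnings = FALSE)
  design <- study$design
  # paths relative to the design file, so the written study is relocatable
  design$fastq_path <- file.path("reads", paste0(design$library_id, ".fastq"))
  readr::write_tsv(design, file.path(out_dir, "design.tsv"))
  for (i in seq_len(nrow(design))) {
    libreads <- filter(study$reads, .data$library_id == design$library_id[i])
    write_fastq(libreads, file.path(out_dir, design$fastq_path[i]))
  }
  write_fasta(setNames(dna_to_rna(study$reference$sequence),
                       study$reference$accession),
              file.path(out_dir, "mirnas.fa"))
  write_fasta(study$genome, file.path(out_dir, "genome.fa"))
  write_fasta(study$transcripts, file.path(out_dir, "transcripts.fa"))
  readr::write_csv(study$ct_table, file.path(out_dir, "ct_table.csv"))
  manifest <- list(
    seed = study$params$seed, preset = study$params$preset,
    families = as.list(setNames(study$truth$mature_sequence,
                                study$truth$family)),
    de_families = study$truth$family[study$truth$is_de],
    loci = purrr::map(seq_len(nrow(study$loci)), function(i) {
      as.list(study$loci[i, ])
    }),
    target_sites = purrr::map(seq_len(nrow(study$target_sites)), function(i) {
      as.list(study$target_sites[i, ])
    })
  )
  yaml::write_yaml(manifest, file.path(out_dir, "truth_manifest.yaml"))
  invisible(out_dir)
}
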