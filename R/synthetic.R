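# Synthetic proteome bundles with planted duplicate families. Similarity
# rows are synthesized directly (no aligner needed), signature rows realize
# each family's domain profile, and a machine-readable manifest records the
# expected groups, classifications and tallies at the strict (>=90%, <=10 aa)
# and relaxed (>=80%, <=10 aa) settings.

VALID_SCENARIOS <- c("true", "incomplete", "space",
                     "near_miss_identity", "near_miss_length")

.default_pfam_pool <- c(
  PF00504 = "Chlorophyll A-B binding protein",
  PF01015 = "Ribosomal protein S3Ae",
  PF00125 = "Core histone H2A/H2B/H3/H4",
  PF11999 = "Ice-binding protein (DUF3494)",
  PF00078 = "Reverse transcriptase"
)

#' Describe one planted duplicate family
#'
#' A family is a set of `copy_count` gene copies planted with a target
#' pairwise identity, a base protein length with bounded jitter, a Pfam
#' domain profile and a scenario that fixes the family's ground-truth fate:
#' \describe{
#'   \item{`true`}{qualifies at the strict setting; identical non-empty
#'     profiles; classified `true`.}
#'   \item{`space`}{qualifies; no copy has any domain; classified `true`
#'     with the space flag.}
#'   \item{`incomplete`}{qualifies; one copy carries an extra domain;
#'     classified `incomplete`.}
#'   \item{`near_miss_identity`}{pairwise identity in \[80, 90); absent at
#'     the strict setting, present at the relaxed one.}
#'   \item{`near_miss_length`}{copy lengths spaced >10 aa apart; absent at
#'     both settings (appears only under larger length bounds).}
#' }
#'
#' @param family_id Unique family label (used as the gene-id prefix).
#' @param copy_count Number of gene copies, >= 2.
#' @param scenario One of `true`, `incomplete`, `space`,
#'   `near_miss_identity`, `near_miss_length`.
#' @param target_identity Planted pairwise identity in percent; defaults to
#'   95 (85 for `near_miss_identity`).
#' @param length_base Base protein length in residues.
#' @param length_jitter Maximum length spread among copies (<= 10 for
#'   qualifying scenarios).
#' @param pfam_profile Character vector of Pfam accessions shared by all
#'   copies; must be empty for `space`, non-empty for `incomplete`.
#' @param ko KEGG Orthology accession for every copy (`NA` = unannotated).
#' @return A list of class `planted_family`.
#' @export
planted_family <- function(family_id, copy_count = 3,
                           scenario = "true",
                           target_identity = if (scenario ==
                             "near_miss_identity") 85 else 95,
                           length_base = 300, length_jitter = 4,
                           pfam_profile = if (scenario == "space")
                             character(0) else "PF00504",
                           ko = NA_character_) {
  scenario <- match.arg(scenario, VALID_SCENARIOS)
  stopifnot(copy_count >= 2, length_base >= 50, length_jitter >= 0)
  if (scenario == "space" && length(pfam_profile) > 0L) {
    stop("space scenario requires an empty pfam_profile", call. = FALSE)
  }
  if (scenario %in% c("true", "incomplete") && length(pfam_profile) == 0L) {
    stop(scenario, " scenario requires a non-empty pfam_profile",
         call. = FALSE)
  }
  if (scenario == "near_miss_identity" &&
      (target_identity < 80 || target_identity >= 90)) {
    stop("near_miss_identity requires target_identity in [80, 90)",
         call. = FALSE)
  }
  if (scenario %in% c("true", "space", "incomplete") && target_identity < 90) {
    stop(scenario, " scenario requires target_identity >= 90", call. = FALSE)
  }
  if (scenario != "near_miss_length" && length_jitter > 10) {
    stop("length_jitter > 10 would break the planted length bound",
         call. = FALSE)
  }
  structure(
    list(family_id = family_id, copy_count = as.integer(copy_count),
         scenario = scenario, target_identity = target_identity,
         length_base = as.integer(length_base),
         length_jitter = as.integer(length_jitter),
         pfam_profile = pfam_profile, ko = ko),
    class = "planted_family"
  )
}

#' Draw a randomized planted-family specification
#'
#' Convenience generator for property tests: `n` families with random
#' scenarios, copy counts 2-5, identities inside each scenario's band and
#' lengths in 150-600 aa. KO accessions rotate through a small pool with
#' some families left unannotated.
#'
#' @param n Number of families.
#' @param seed Integer seed (the caller's RNG state is not touched).
#' @return List of [planted_family()] objects.
#' @export
random_family_spec <- function(n, seed) {
  stopifnot(n >= 1)
  rng <- .with_seed(seed, {
    scen <- sample(VALID_SCENARIOS, n, replace = TRUE)
    copies <- sample(2:5, n, replace = TRUE)
    bases <- sample(150:600, n, replace = TRUE)
    ident_hi <- round(stats::runif(n, 91, 99), 1)
    ident_lo <- round(stats::runif(n, 81, 89), 1)
    nprof <- sample(1:3, n, replace = TRUE)
    profs <- lapply(nprof, function(k)
      sort(sample(names(.default_pfam_pool), k)))
    kos <- sample(c("K02639", "K13979", "K02868", "K01054", NA), n,
                  replace = TRUE)
    jitters <- sample(0:6, n, replace = TRUE)
    list(scen = scen, copies = copies, bases = bases, ident_hi = ident_hi,
         ident_lo = ident_lo, profs = profs, kos = kos, jitters = jitters)
  })
  lapply(seq_len(n), function(i) {
    scen <- rng$scen[i]
    planted_family(
      family_id = sprintf("fam%03d", i),
      copy_count = rng$copies[i],
      scenario = scen,
      target_identity = if (scen == "near_miss_identity")
        rng$ident_lo[i] else rng$ident_hi[i],
      length_base = rng$bases[i],
      length_jitter = if (scen == "near_miss_length") 0L else rng$jitters[i],
      pfam_profile = if (scen == "space") character(0) else rng$profs[[i]],
      ko = rng$kos[i]
    )
  })
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

.random_protein <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], len,
               replace = TRUE), collapse = "")
}

.family_lengths <- function(fam) {
  k <- fam$copy_count
  if (fam$scenario == "near_miss_length") {
    # every pairwise difference exceeds 10 aa
    fam$length_base + (seq_len(k) - 1L) * 12L
  } else {
    jit <- sample(0:fam$length_jitter, k, replace = TRUE)
    fam$length_base + jit
  }
}

.pfam_to_ipr <- function(acc) sub("^PF", "IPR0", acc)

#' Generate a synthetic proteome bundle with planted HSD structure
#'
#' Writes five plain-text files into `dir` — `proteome.fasta`,
#' `similarity.tsv` (12-column), `signatures.tsv` (13-column), `ko.tsv`
#' (two-column) and `category_map.tsv` — plus `manifest.json` recording the
#' ground truth. Similarity rows cover every within-family pair (identity
#' drawn inside the scenario's band, E-value far below 1e-5), self-hits at
#' 100% identity, reverse-direction duplicates at lower bit score, and
#' decoy cross-family rows failing either the identity or the E-value
#' filter. Copies of `space`-scenario families carry no signature rows, so
#' their lengths are only recoverable from the FASTA. Generation is
#' deterministic: the same `families` and `seed` give a byte-identical
#' bundle.
#'
#' @param families List of [planted_family()] objects with unique ids.
#' @param seed Integer seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the five file `paths`, the `manifest`
#'   (also written as JSON), and `genes` (the planted per-gene table).
#' @export
generate_hsd_dataset <- function(families, seed, dir) {
  stopifnot(length(families) > 0L,
            all(vapply(families, inherits, logical(1L), "planted_family")))
  ids <- vapply(families, `[[`, character(1L), "family_id")
  if (anyDuplicated(ids)) stop("duplicate family ids", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)

  .with_seed(seed, {
    gene_rows <- list()
    sim_lines <- character(0)
    sig_lines <- character(0)
    fasta_lines <- character(0)
    ko_lines <- character(0)

    for (fam in families) {
      k <- fam$copy_count
      gid <- sprintf("%s_c%02d", fam$family_id, seq_len(k))
      lens <- .family_lengths(fam)
      profiles <- rep(list(fam$pfam_profile), k)
      if (fam$scenario == "incomplete") {
        # first copy carries one extra domain the others lack
        extra <- setdiff(names(.default_pfam_pool), fam$pfam_profile)
        if (length(extra) == 0L) extra <- "PF99999"
        profiles[[1L]] <- sort(c(fam$pfam_profile, extra[1L]))
      }
      gene_rows[[fam$family_id]] <- data.frame(
        gene_id = gid, family_id = fam$family_id, length = lens,
        scenario = fam$scenario, stringsAsFactors = FALSE)

      # FASTA for every copy
      for (i in seq_len(k)) {
        fasta_lines <- c(fasta_lines, paste0(">", gid[i]),
                         .random_protein(lens[i]))
      }
      # signature rows (none for space families: FASTA is the length source)
      if (fam$scenario != "space") {
        for (i in seq_len(k)) {
          for (acc in profiles[[i]]) {
            desc <- if (acc %in% names(.default_pfam_pool))
              .default_pfam_pool[[acc]] else "Planted domain"
            dom_len <- max(20L, lens[i] %/% 3L)
            start <- sample(seq_len(max(1L, lens[i] - dom_len)), 1L)
            sig_lines <- c(sig_lines, paste(
              gid[i], "md5", lens[i], "Pfam", acc, desc,
              start, start + dom_len - 1L, "1.0E-30", "T", "2021-01-01",
              .pfam_to_ipr(acc), desc, sep = "\t"))
          }
        }
      }
      # within-family similarity: every unordered pair, forward + a weaker
      # reverse-direction duplicate, plus a 100%-identity self-hit per copy
      band <- if (fam$scenario == "near_miss_identity")
        c(max(80, fam$target_identity - 2), min(89.9, fam$target_identity + 2))
      else c(max(90, fam$target_identity - 2), min(99.9, fam$target_identity + 2))
      for (i in seq_len(k)) {
        aln <- lens[i]
        sim_lines <- c(sim_lines, paste(
          gid[i], gid[i], "100.0", aln, 0L, 0L, 1L, aln, 1L, aln,
          "0.0", format(round(2 * aln, 1), nsmall = 1), sep = "\t"))
        if (i < k) for (j in (i + 1L):k) {
          ident <- round(stats::runif(1L, band[1L], band[2L]), 1)
          aln <- min(lens[i], lens[j])
          mism <- round(aln * (1 - ident / 100))
          bits <- round(1.9 * aln - mism, 1)
          sim_lines <- c(sim_lines, paste(
            gid[i], gid[j], format(ident, nsmall = 1), aln, mism, 0L,
            1L, aln, 1L, aln, "1e-80",
            format(bits, nsmall = 1), sep = "\t"))
          sim_lines <- c(sim_lines, paste(
            gid[j], gid[i], format(max(80, ident - 0.5), nsmall = 1),
            aln, mism, 0L, 1L, aln, 1L, aln, "1e-70",
            format(bits - 5, nsmall = 1), sep = "\t"))
        }
      }
      # KO assignment
      for (g in gid) {
        ko_lines <- c(ko_lines, paste0(g, "\t",
                                       if (is.na(fam$ko)) "" else fam$ko))
      }
    }

    genes <- do.call(rbind, gene_rows)
    rownames(genes) <- NULL

    # decoy cross-family rows: fail identity or fail E-value
    fam_first <- vapply(split(genes$gene_id, genes$family_id),
                        `[`, character(1L), 1L)
    if (length(fam_first) >= 2L) {
      for (i in seq_len(length(fam_first) - 1L)) {
        a <- fam_first[[i]]; b <- fam_first[[i + 1L]]
        la <- genes$length[genes$gene_id == a]
        aln <- max(30L, la %/% 2L)
        sim_lines <- c(sim_lines, paste(
          a, b, "42.5", aln, round(aln * 0.575), 2L, 1L, aln, 1L, aln,
          "1e-20", format(round(0.8 * aln, 1), nsmall = 1), sep = "\t"))
        sim_lines <- c(sim_lines, paste(
          a, b, "95.0", 30L, 1L, 0L, 1L, 30L, 1L, 30L,
          "1.0", "25.0", sep = "\t"))
      }
    }

    paths <- list(
      fasta = file.path(dir, "proteome.fasta"),
      similarity = file.path(dir, "similarity.tsv"),
      signatures = file.path(dir, "signatures.tsv"),
      ko = file.path(dir, "ko.tsv"),
      category_map = file.path(dir, "category_map.tsv"),
      manifest = file.path(dir, "manifest.json")
    )
    writeLines(fasta_lines, paths$fasta)
    writeLines(sim_lines, paths$similarity)
    writeLines(sig_lines, paths$signatures)
    writeLines(ko_lines, paths$ko)
    writeLines(.default_category_map_lines(), paths$category_map)

    manifest <- .build_manifest(families, genes)
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    invisible(list(paths = paths, manifest = manifest, genes = genes))
  })
}

.default_category_map_lines <- function() {
  c("K02639\t09102\tEnergy metabolism\tferredoxin",
    "K13979\t09101\tCarbohydrate metabolism\talcohol dehydrogenase",
    "K02868\t09122\tTranslation\tlarge subunit ribosomal protein L11e",
    "K01054\t09103\tLipid metabolism\tacylglycerol lipase",
    # one KO mapping to two categories exercises multi-category listing
    "K08913\t09102\tEnergy metabolism\tlight-harvesting complex II protein",
    "K08913\t09104\tPhotosynthesis proteins\tlight-harvesting complex II protein")
}

.expected_groups <- function(families, genes, relaxed) {
  qualifies <- vapply(families, function(fam) {
    switch(fam$scenario,
           "true" = , "space" = , "incomplete" = TRUE,
           "near_miss_identity" = relaxed,
           "near_miss_length" = FALSE)
  }, logical(1L))
  fams <- families[qualifies]
  if (length(fams) == 0L) {
    return(list(groups = list(), tally = list(candidate = 0L, true_count = 0L,
                                              space = 0L, incomplete = 0L),
                histogram = list(groups_2 = 0L, groups_3 = 0L,
                                 groups_4plus = 0L)))
  }
  groups <- lapply(fams, function(fam) {
    members <- sort(genes$gene_id[genes$family_id == fam$family_id])
    list(group_id = members[1L], members = members,
         classification = if (fam$scenario == "incomplete")
           "incomplete" else "true",
         space_flag = fam$scenario == "space",
         ko = if (is.na(fam$ko)) "" else fam$ko)
  })
  groups <- groups[order(vapply(groups, `[[`, character(1L), "group_id"))]
  sizes <- vapply(groups, function(g) length(g$members), integer(1L))
  cls <- vapply(groups, `[[`, character(1L), "classification")
  spc <- vapply(groups, `[[`, logical(1L), "space_flag")
  list(
    groups = groups,
    tally = list(candidate = length(groups),
                 true_count = sum(cls == "true"),
                 space = sum(spc),
                 incomplete = sum(cls == "incomplete")),
    histogram = list(groups_2 = sum(sizes == 2L),
                     groups_3 = sum(sizes == 3L),
                     groups_4plus = sum(sizes >= 4L))
  )
}

.build_manifest <- function(families, genes) {
  list(
    n_families = length(families),
    n_genes = nrow(genes),
    families = lapply(families, function(fam) {
      fam_genes <- genes[genes$family_id == fam$family_id, , drop = FALSE]
      list(family_id = fam$family_id, scenario = fam$scenario,
           copy_count = fam$copy_count,
           gene_ids = fam_genes$gene_id, lengths = fam_genes$length,
           pfam_profile = fam$pfam_profile,
           ko = if (is.na(fam$ko)) "" else fam$ko)
    }),
    default = .expected_groups(families, genes, relaxed = FALSE),
    relaxed = .expected_groups(families, genes, relaxed = TRUE)
  )
}

# ---------------------------------------------------------------------------
# Independent brute-force reference pipeline (naive double loops; iterated
# transitive closure instead of a graph library). Intended for small
# instances (<= 500 genes) as a cross-check of the main implementation.

#' Brute-force reference run of the HSD pipeline
#'
#' Recomputes qualifying pairs by a naive scan over all hit rows and groups
#' them by iterated set merging (transitive closure), then classifies and
#' tallies. Shares no clustering code with [cluster_groups()]; intended as
#' an independent cross-check on small instances.
#'
#' @param hits Similarity table.
#' @param genes Gene records from [build_gene_records()].
#' @param cfg Thresholds from [threshold_config()].
#' @return List with `groups` (list of sorted member vectors, ordered by
#'   smallest member), `tally` and `histogram`.
#' @export
brute_force_pipeline <- function(hits, genes, cfg = threshold_config()) {
  len <- stats::setNames(genes$length, genes$gene_id)
  # best hit per unordered pair, naive accumulation
  best <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(hits))) {
    q <- hits$query_id[r]; s <- hits$subject_id[r]
    if (q == s) next
    key <- paste(sort(c(q, s)), collapse = "\r")
    prev <- if (!is.null(best[[key]])) best[[key]] else NULL
    if (is.null(prev) || hits$bit_score[r] > prev$bit) {
      best[[key]] <- list(a = min(q, s), b = max(q, s),
                          id = hits$percent_identity[r],
                          ev = hits$e_value[r], bit = hits$bit_score[r])
    }
  }
  pairs <- list()
  for (key in ls(best)) {
    h <- best[[key]]
    la <- len[h$a]; lb <- len[h$b]
    if (h$ev <= cfg$evalue_max && h$id >= cfg$identity_min &&
        !is.na(la) && !is.na(lb) && abs(la - lb) <= cfg$length_diff_max) {
      pairs[[length(pairs) + 1L]] <- c(h$a, h$b)
    }
  }
  groups <- brute_force_components(pairs)
  # naive classification
  idx <- stats::setNames(seq_len(nrow(genes)), genes$gene_id)
  cls <- character(length(groups)); spc <- logical(length(groups))
  for (i in seq_along(groups)) {
    profs <- genes$pfam_profile[idx[groups[[i]]]]
    same <- TRUE
    for (p in profs) if (!identical(p, profs[[1L]])) same <- FALSE
    cls[i] <- if (same) "true" else "incomplete"
    spc[i] <- same && length(profs[[1L]]) == 0L
  }
  sizes <- lengths(groups)
  list(
    groups = groups,
    tally = list(candidate = length(groups),
                 true_count = sum(cls == "true"), space = sum(spc),
                 incomplete = sum(cls == "incomplete")),
    histogram = list(groups_2 = sum(sizes == 2L), groups_3 = sum(sizes == 3L),
                     groups_4plus = sum(sizes >= 4L),
                     copies_2 = sum(sizes[sizes == 2L]),
                     copies_3 = sum(sizes[sizes == 3L]),
                     copies_4plus = sum(sizes[sizes >= 4L]))
  )
}

#' Connected components by iterated set merging
#'
#' Repeatedly merges overlapping member sets until a fixed point — a
#' transitive-closure computation independent of any graph library.
#'
#' @param pairs List of length-2 character vectors (edges).
#' @return List of sorted member vectors, ordered by smallest member.
#' @export
brute_force_components <- function(pairs) {
  sets <- lapply(pairs, function(p) sort(unique(p)))
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < length(sets)) {
      j <- i + 1L
      while (j <= length(sets)) {
        if (length(intersect(sets[[i]], sets[[j]])) > 0L) {
          sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
          sets[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
      i <- i + 1L
    }
    if (!merged) break
  }
  sets[order(vapply(sets, `[`, character(1L), 1L))]
}
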