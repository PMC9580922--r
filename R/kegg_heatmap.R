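# KEGG pathway-category aggregation of HSD groups across species, and the
# cross-species heatmap.

#' Assign a KEGG Orthology accession to an HSD group
#'
#' The group-level KO is the accession shared by the majority of the
#' annotated members; ties break to the lexicographically smallest KO.
#' Members without an assignment do not vote. When no member is annotated
#' the group has no KO.
#'
#' @param members Character vector of member gene ids.
#' @param ko Data frame from [read_ko_file()].
#' @return A single KO accession, or `NA_character_` when no member carries
#'   one.
#' @export
#' @examples
#' ko <- data.frame(gene_id = c("g1", "g2", "g3"),
#'                  ko_accession = c("K02639", "K02639", ""))
#' assign_group_ko(c("g1", "g2", "g3"), ko)  # "K02639"
assign_group_ko <- function(members, ko) {
  acc <- ko$ko_accession[match(members, ko$gene_id)]
  acc <- acc[!is.na(acc) & nzchar(acc)]
  if (length(acc) == 0L) return(NA_character_)
  tab <- table(acc)
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[1L]
}

#' Categorize HSD groups under KEGG pathway functional categories
#'
#' For each species, every group is assigned a KO by majority vote over its
#' members and then listed once under every pathway category that KO maps
#' to. Groups without any KO fall under the `Unassigned` pseudo-category;
#' groups whose KO is missing from the category map fall under `Unmapped`
#' (with a warning). The cross-species count matrix holds the number of
#' distinct HSD groups per (species, category) cell.
#'
#' @param groups_by_species Named list: species -> group table from
#'   [cluster_groups()] or [read_hsd_table()].
#' @param ko_by_species Named list: species -> KO table from
#'   [read_ko_file()]. Names must cover `groups_by_species`.
#' @param category_map Data frame from [read_category_map()].
#' @return A list with `table` (one row per species x group x category:
#'   `species`, `category_id`, `category_name`, `ko_accession`,
#'   `ko_description`, `group_id`, `copy_count`, `member_ids`) and `matrix`
#'   (integer matrix, categories in rows, species in columns, both sorted).
#' @export
categorize_hsds <- function(groups_by_species, ko_by_species, category_map) {
  stopifnot(all(names(groups_by_species) %in% names(ko_by_species)))
  rows <- list()
  unmapped <- character(0)
  for (sp in names(groups_by_species)) {
    groups <- groups_by_species[[sp]]
    ko <- ko_by_species[[sp]]
    for (i in seq_len(nrow(groups))) {
      members <- groups$members[[i]]
      acc <- assign_group_ko(members, ko)
      if (is.na(acc)) {
        cats <- data.frame(category_id = "Unassigned",
                           category_name = "No KO annotation",
                           ko_description = "", stringsAsFactors = FALSE)
        acc_out <- ""
      } else {
        hit <- category_map[category_map$ko_accession == acc, , drop = FALSE]
        if (nrow(hit) == 0L) {
          unmapped <- c(unmapped, acc)
          cats <- data.frame(category_id = "Unmapped",
                             category_name = "KO not in category map",
                             ko_description = "", stringsAsFactors = FALSE)
        } else {
          cats <- hit[, c("category_id", "category_name", "ko_description")]
        }
        acc_out <- acc
      }
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp,
        category_id = cats$category_id,
        category_name = cats$category_name,
        ko_accession = acc_out,
        ko_description = cats$ko_description,
        group_id = groups$group_id[i],
        copy_count = length(members),
        member_ids = paste(members, collapse = ";"),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(unmapped) > 0L) {
    warning("KO(s) absent from category map, counted under 'Unmapped': ",
            paste(sort(unique(unmapped)), collapse = ", "))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), category_id = character(0),
               category_name = character(0), ko_accession = character(0),
               ko_description = character(0), group_id = character(0),
               copy_count = integer(0), member_ids = character(0),
               stringsAsFactors = FALSE)
  tab <- tab[order(tab$species, tab$category_id, tab$group_id), , drop = FALSE]
  rownames(tab) <- NULL

  species <- sort(names(groups_by_species))
  cat_key <- unique(tab[, c("category_id", "category_name")])
  cat_key <- cat_key[order(cat_key$category_id), , drop = FALSE]
  cat_lab <- if (nrow(cat_key)) paste(cat_key$category_id,
                                      cat_key$category_name) else character(0)
  mat <- matrix(0L, nrow = nrow(cat_key), ncol = length(species),
                dimnames = list(cat_lab, species))
  for (i in seq_len(nrow(tab))) {
    r <- match(tab$category_id[i], cat_key$category_id)
    c <- match(tab$species[i], species)
    mat[r, c] <- mat[r, c] + 1L
  }
  list(table = tab, matrix = mat)
}

#' Write the categorized-HSD table as an 8-column TSV
#'
#' Columns: species, category_id, category_name, ko_accession,
#' ko_description, group_id, copy_count, member_ids.
#'
#' @param categorized The `table` element of [categorize_hsds()] output.
#' @param path Output path.
#' @param provenance Optional `#`-comment provenance lines.
#' @return Invisibly, `path`.
#' @export
write_categorized_table <- function(categorized, path, provenance = NULL) {
  cols <- c("species", "category_id", "category_name", "ko_accession",
            "ko_description", "group_id", "copy_count", "member_ids")
  stopifnot(all(cols %in% names(categorized)))
  lines <- character(0)
  if (!is.null(provenance)) lines <- paste0("# ", provenance)
  lines <- c(lines, paste0("# ", paste(cols, collapse = "\t")))
  if (nrow(categorized) > 0L) {
    m <- as.matrix(categorized[, cols])
    lines <- c(lines, apply(m, 1L, function(r) paste(trimws(r), collapse = "\t")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Render the cross-species KEGG-category heatmap
#'
#' A tile heatmap of HSD-group counts with species as columns and pathway
#' categories as rows, linear color scale, each cell annotated with its
#' count. Written as PNG and SVG.
#'
#' @param mat Count matrix from [categorize_hsds()] (`$matrix`).
#' @param path Output path; extension replaced by `.png` / `.svg`.
#' @param width,height Figure size in inches.
#' @return Invisibly, the two file paths written.
#' @export
render_kegg_heatmap <- function(mat, path, width = 8, height = 6) {
  if (length(mat) == 0L) stop("empty category matrix", call. = FALSE)
  d <- expand.grid(category = rownames(mat), species = colnames(mat),
                   stringsAsFactors = FALSE)
  d$count <- as.vector(mat)
  d$category <- factor(d$category, levels = rev(rownames(mat)))
  d$species <- factor(d$species, levels = colnames(mat))
  fig <- ggplot2::ggplot(d, ggplot2::aes(x = .data$species,
                                         y = .data$category,
                                         fill = .data$count)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "#fff7ec", high = "#b2182b",
                                 name = "HSD groups") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  base <- sub("\\.[A-Za-z]+$", "", path)
  png_path <- paste0(base, ".png")
  svg_path <- paste0(base, ".svg")
  ggplot2::ggsave(png_path, fig, width = width, height = height, dpi = 150)
  grDevices::svg(svg_path, width = width, height = height)
  print(fig)
  grDevices::dev.off()
  invisible(c(png_path, svg_path))
}
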