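# Threshold-sweep evaluation: capturing value, performance score, the
# identity-by-length grid, and the sweep figure.

#' Capturing value of a classified HSD set
#'
#' The percentage of candidate groups whose copies share identical domain
#' content: `100 * true / (true + incomplete)`, truncated to an integer
#' (floor). Set `precise = TRUE` for the untruncated value.
#'
#' @param true_count Number of domain-consistent (`true`) groups.
#' @param incomplete Number of domain-discordant (`incomplete`) groups.
#' @param precise Return the untruncated percentage instead of the floored
#'   integer.
#' @return Integer percentage in \[0, 100\] (or a double when
#'   `precise = TRUE`).
#' @export
#' @examples
#' capturing_value(7294, 110)  # 98
#' capturing_value(8245, 402)  # 95
capturing_value <- function(true_count, incomplete, precise = FALSE) {
  stopifnot(true_count >= 0, incomplete >= 0)
  denom <- true_count + incomplete
  if (any(denom == 0)) {
    stop("capturing value undefined: no candidate groups", call. = FALSE)
  }
  val <- 100 * true_count / denom
  if (precise) val else as.integer((100 * true_count) %/% denom)
}

#' Performance score of a classified HSD set
#'
#' `(2*true + incomplete - space) / (incomplete + 1)`, truncated to an
#' integer (floor). The numerator rewards domain-consistent groups and
#' groups carrying any functional domain (`true + (true + incomplete -
#' space)`); the `+1` in the denominator avoids division by zero when no
#' group is discordant. Set `precise = TRUE` for the untruncated value.
#'
#' @param true_count Number of `true` groups.
#' @param incomplete Number of `incomplete` groups.
#' @param space Number of groups in which no copy carries any domain.
#' @param precise Return the untruncated ratio instead of the floored
#'   integer.
#' @return Integer score (or a double when `precise = TRUE`).
#' @export
#' @examples
#' performance_score(7294, 110, 1371)  # 120
#' performance_score(7787, 183, 1427)  # 77
performance_score <- function(true_count, incomplete, space,
                              precise = FALSE) {
  stopifnot(true_count >= 0, incomplete >= 0, space >= 0)
  num <- 2 * true_count + incomplete - space
  denom <- incomplete + 1
  if (precise) num / denom else as.integer(num %/% denom)
}

#' Sweep HSD detection over an identity-by-length threshold grid
#'
#' Re-runs the full pipeline (filter, cluster, classify, tally) at every
#' combination of identity and length-difference threshold and computes the
#' evaluation statistics per cell. The default grid is 4 identities x 5
#' length bounds = 20 cells.
#'
#' @param hits Similarity table from [read_similarity_table()].
#' @param genes Gene records from [build_gene_records()].
#' @param identity_grid Identity thresholds in percent.
#' @param length_grid Length-difference bounds in amino acids.
#' @param evalue_max E-value bound applied at every cell.
#' @param profile Domain profile passed to [classify_groups()].
#' @return Data frame with one row per cell: `identity_min`,
#'   `length_diff_max`, `candidate`, `true_count`, `space`, `incomplete`,
#'   `capturing_value`, `performance_score` (floored integers),
#'   `capturing_value_precise`, `performance_score_precise`, and copy-number
#'   bins `groups_2`, `groups_3`, `groups_4plus`, `copies_2`, `copies_3`,
#'   `copies_4plus`. Rows ordered identity-major, ascending.
#' @export
threshold_sweep <- function(hits, genes,
                            identity_grid = c(60, 70, 80, 90),
                            length_grid = c(10, 30, 50, 70, 100),
                            evalue_max = 1e-5,
                            profile = "pfam") {
  stopifnot(length(identity_grid) > 0L, length(length_grid) > 0L)
  cells <- expand.grid(length_diff_max = sort(length_grid),
                       identity_min = sort(identity_grid))
  cells <- cells[order(cells$identity_min, cells$length_diff_max), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cfg <- threshold_config(identity_min = cells$identity_min[i],
                            length_diff_max = cells$length_diff_max[i],
                            evalue_max = evalue_max)
    edges <- filter_edges(hits, genes, cfg)
    groups <- classify_groups(cluster_groups(edges), genes, profile = profile)
    tal <- tally_classifications(groups)
    hist <- copy_number_histogram(groups)
    cap <- if (tal$candidate > 0)
      capturing_value(tal$true_count, tal$incomplete) else NA_integer_
    cap_p <- if (tal$candidate > 0)
      capturing_value(tal$true_count, tal$incomplete, precise = TRUE)
    else NA_real_
    data.frame(
      identity_min = cfg$identity_min,
      length_diff_max = cfg$length_diff_max,
      candidate = tal$candidate, true_count = tal$true_count,
      space = tal$space, incomplete = tal$incomplete,
      capturing_value = cap,
      performance_score = performance_score(tal$true_count, tal$incomplete,
                                            tal$space),
      capturing_value_precise = cap_p,
      performance_score_precise = performance_score(
        tal$true_count, tal$incomplete, tal$space, precise = TRUE),
      groups_2 = hist$groups_2, groups_3 = hist$groups_3,
      groups_4plus = hist$groups_4plus,
      copies_2 = hist$copies_2, copies_3 = hist$copies_3,
      copies_4plus = hist$copies_4plus,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a sweep grid as a tab-delimited summary table
#'
#' One row per threshold cell with the columns laid out as a threshold label
#' (`90%_10aa` style), candidate / true / space / incomplete counts,
#' capturing value, score, and the 2 / 3 / >=4 copy-number bins.
#'
#' @param sweep Data frame from [threshold_sweep()].
#' @param path Output path.
#' @param species Optional species label written as the first column.
#' @return Invisibly, `path`.
#' @export
write_sweep_table <- function(sweep, path, species = NULL) {
  lab <- sprintf("%g%%_%gaa", sweep$identity_min, sweep$length_diff_max)
  out <- data.frame(
    thresholds = lab,
    candidate_hsds = sweep$candidate,
    true_hsds = sweep$true_count,
    space = sweep$space,
    incomplete_hsds = sweep$incomplete,
    capturing_value_pct = sweep$capturing_value,
    score = sweep$performance_score,
    groups_2 = sweep$groups_2,
    groups_3 = sweep$groups_3,
    groups_4plus = sweep$groups_4plus,
    stringsAsFactors = FALSE
  )
  if (!is.null(species)) out <- cbind(species = species, out)
  header <- paste0("# ", paste(names(out), collapse = "\t"))
  body <- apply(out, 1L, function(r) paste(trimws(r), collapse = "\t"))
  writeLines(c(header, as.character(body)), path)
  invisible(path)
}

#' Reference threshold-grid statistics for Arabidopsis thaliana
#'
#' Loads the reference grid of HSD counts for the A. thaliana proteome
#' shipped with the package: candidate / true / space / incomplete group
#' counts, the printed capturing value and score, and copy-number bins at
#' all 20 combinations of identity (60, 70, 80, 90%) and length-difference
#' (10, 30, 50, 70, 100 aa) thresholds. Used to validate the evaluation
#' statistics against a genome-scale result without redistributing the
#' proteome itself.
#'
#' @return Data frame with columns `identity_min`, `length_diff_max`,
#'   `candidate`, `true_count`, `space`, `incomplete`, `capturing_value`,
#'   `score`, `groups_2`, `groups_3`, `groups_4plus`.
#' @export
reference_sweep_stats <- function() {
  path <- system.file("extdata", "athaliana_threshold_counts.tsv",
                      package = "hsdetect", mustWork = TRUE)
  dat <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           stringsAsFactors = FALSE)
  dat
}

#' Render the threshold-sweep figure
#'
#' A heatmap of true-HSD counts over the identity-by-length grid (blue =
#' lowest to red = highest, cells annotated with the count), flanked by a
#' top bar panel of capturing values (bars grouped by identity threshold)
#' and a left bar panel of performance scores (grouped by length bound).
#' Written as both PNG and SVG beside each other.
#'
#' @param sweep Data frame from [threshold_sweep()] covering a full
#'   rectangular grid.
#' @param path Output path; the extension is replaced by `.png` and `.svg`.
#' @param width,height Figure size in inches.
#' @return Invisibly, the two file paths written.
#' @export
render_sweep_figure <- function(sweep, path, width = 9, height = 7) {
  ids <- sort(unique(sweep$identity_min))
  lens <- sort(unique(sweep$length_diff_max))
  if (nrow(sweep) != length(ids) * length(lens)) {
    stop("sweep grid is not rectangular", call. = FALSE)
  }
  d <- sweep
  d$id_f <- factor(sprintf("%g%%", d$identity_min),
                   levels = sprintf("%g%%", ids))
  d$len_f <- factor(sprintf("%g aa", d$length_diff_max),
                    levels = sprintf("%g aa", lens))

  midpoint <- mean(range(d$true_count))
  heat <- ggplot2::ggplot(d, ggplot2::aes(x = .data$len_f, y = .data$id_f,
                                          fill = .data$true_count)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$true_count), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "#f7f7f7",
                                  high = "#b2182b", midpoint = midpoint,
                                  name = "True HSDs") +
    ggplot2::labs(x = "Length-difference threshold",
                  y = "Identity threshold") +
    ggplot2::theme_minimal()

  top <- ggplot2::ggplot(d, ggplot2::aes(x = .data$len_f,
                                         y = .data$capturing_value,
                                         fill = .data$id_f)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_brewer(palette = "Set2", name = "Identity") +
    ggplot2::labs(x = NULL, y = "Capturing value (%)") +
    ggplot2::theme_minimal()

  left <- ggplot2::ggplot(d, ggplot2::aes(x = .data$id_f,
                                          y = .data$performance_score,
                                          fill = .data$len_f)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::scale_fill_brewer(palette = "Set3", name = "Length") +
    ggplot2::labs(x = NULL, y = "Performance score") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()

  fig <- (top | patchwork::plot_spacer()) / (heat | left) +
    patchwork::plot_layout(heights = c(1, 2), widths = c(2, 1))

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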