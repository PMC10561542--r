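# Plain-text exporters for the pipeline's tabular outputs.

#' Write a data frame as TSV
#' @param x data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export cluster assignment tables
#'
#' Writes the membership table (electrode, cluster, hemisphere) and the
#' per-cluster landmark table (start/onset/peak/offset/end) as TSV.
#'
#' @param assignment a [assign_clusters()] result.
#' @param electrode_meta electrode metadata aligned with the profiles.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cluster_tables <- function(assignment, electrode_meta, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  members <- data.frame(electrode = electrode_meta$id,
                        cluster = assignment$membership,
                        hemisphere = electrode_meta$hemisphere)
  lm <- do.call(rbind, lapply(seq_along(assignment$landmarks), function(i) {
    l <- assignment$landmarks[[i]]
    if (is.null(l)) return(NULL)
    data.frame(cluster = i, start_ms = l$start_ms, onset_slope = l$onset_slope,
               peak_ms = l$peak_ms, offset_slope = l$offset_slope,
               end_ms = l$end_ms, censored = l$censored)
  }))
  p1 <- file.path(dir, "cluster_membership.tsv")
  p2 <- file.path(dir, "cluster_landmarks.tsv")
  write_tsv_table(members, p1)
  if (!is.null(lm)) write_tsv_table(lm, p2)
  invisible(c(p1, p2))
}

#' Export change-point tables
#'
#' One row per change point: electrode, time (ms), and the slope of the
#' segment the change opens.
#'
#' @param series named list of `trend_series`, one per electrode.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_change_points <- function(series, path) {
  rows <- do.call(rbind, lapply(names(series), function(id) {
    s <- series[[id]]
    if (!nrow(s$change_points)) return(NULL)
    slopes <- s$segments$slope_per_s[match(s$change_points$time_ms,
                                           s$segments$start_ms)]
    data.frame(electrode = id, time_ms = s$change_points$time_ms,
               slope_per_s = slopes)
  }))
  if (is.null(rows)) {
    rows <- data.frame(electrode = character(0), time_ms = numeric(0),
                       slope_per_s = numeric(0))
  }
  write_tsv_table(rows, path)
}
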