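#' Write / read a multi-TI stack as plain text
#'
#' Working format of the pipeline: a directory holding `stack.csv`
#' (long format: `phase_index`, `ti_index`, `row`, `col`, `value`; indices
#' 0-based), `ti_table.csv` (`phase_index`, `ti_index`, `ti_ms`), and
#' `meta.json` (shape + acquisition provenance). Values are written in
#' full double precision so a round trip is lossless.
#'
#' @param stack A [multi_ti_stack()].
#' @param dir Output directory (created if missing).
#' @return `write_stack` returns `dir` invisibly; `read_stack` the
#'   reconstructed `multi_ti_stack`.
#' @export
write_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "multi_ti_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$data)
  grid <- expand.grid(phase_index = seq_len(d[1]) - 1L,
                      ti_index = seq_len(d[2]) - 1L,
                      row = seq_len(d[3]) - 1L,
                      col = seq_len(d[4]) - 1L)
  grid$value <- as.vector(stack$data)
  utils::write.csv(format_num(grid), file.path(dir, "stack.csv"),
                   row.names = FALSE, quote = FALSE)
  write_ti_csv(stack$ti_table, file.path(dir, "ti_table.csv"))
  meta <- stack$meta
  meta$shape <- d
  jsonlite::write_json(serialize_meta(meta), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

format_num <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- format(df[[nm]], digits = 17, trim = TRUE)
  }
  df
}

serialize_meta <- function(x) {
  if (is.list(x)) return(lapply(unclass(x), serialize_meta))
  x
}

#' @rdname write_stack
#' @export
read_stack <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  d <- as.integer(meta$shape)
  df <- utils::read.csv(file.path(dir, "stack.csv"))
  need <- c("phase_index", "ti_index", "row", "col", "value")
  if (!all(need %in% names(df))) stop("stack.csv missing columns")
  if (nrow(df) != prod(d)) stop("stack.csv row count does not match shape")
  arr <- array(NA_real_, d)
  arr[cbind(df$phase_index + 1L, df$ti_index + 1L, df$row + 1L, df$col + 1L)] <-
    df$value
  ti <- read_ti_csv(file.path(dir, "ti_table.csv"))
  if (nrow(ti) != d[1] || ncol(ti) != d[2]) {
    stop("TI table does not match stack shape (phase/TI count mismatch)")
  }
  meta$shape <- NULL
  multi_ti_stack(arr, ti, meta = meta)
}

#' Write / read a TI table CSV
#'
#' Columns `phase_index` (0-based), `ti_index` (0-based), `ti_ms`.
#'
#' @param ti_table Matrix `[phase, ti]` of inversion times (ms).
#' @param path CSV path.
#' @return `write_ti_csv`: `path` invisibly; `read_ti_csv`: the matrix.
#' @export
write_ti_csv <- function(ti_table, path) {
  stopifnot(is.matrix(ti_table))
  df <- expand.grid(phase_index = seq_len(nrow(ti_table)) - 1L,
                    ti_index = seq_len(ncol(ti_table)) - 1L)
  df$ti_ms <- as.vector(ti_table)
  utils::write.csv(format_num(df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ti_csv
#' @export
read_ti_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("phase_index", "ti_index", "ti_ms")
  if (!all(need %in% names(df))) stop("TI CSV must have columns ",
                                      paste(need, collapse = ", "))
  n_phase <- max(df$phase_index) + 1L
  n_ti <- max(df$ti_index) + 1L
  if (nrow(df) != n_phase * n_ti) stop("TI CSV is not a full phase x TI grid")
  m <- matrix(NA_real_, n_phase, n_ti)
  m[cbind(df$phase_index + 1L, df$ti_index + 1L)] <- df$ti_ms
  m
}

#' Write / read fitted maps as plain text
#'
#' `maps.csv` holds one row per fitted voxel per phase with columns
#' `phase_index`, `row`, `col` (0-based), `a`, `t1_star_ms`, `sse`,
#' `polarity_k`, `converged`; unfitted voxels are absent (flagged `NA` on
#' read). The mask, TI table and provenance travel alongside.
#'
#' @param maps A `t1star_maps` object.
#' @param dir Output directory.
#' @return `write_maps`: `dir` invisibly; `read_maps`: the object.
#' @export
write_maps <- function(maps, dir) {
  stopifnot(inherits(maps, "t1star_maps"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(maps$t1_star_map)
  keep <- which(!is.na(maps$t1_star_map) | !is.na(maps$a_map), arr.ind = TRUE)
  df <- data.frame(phase_index = keep[, 1] - 1L, row = keep[, 2] - 1L,
                   col = keep[, 3] - 1L,
                   a = maps$a_map[keep], t1_star_ms = maps$t1_star_map[keep],
                   sse = maps$sse_map[keep], polarity_k = maps$polarity_map[keep],
                   converged = maps$converged_map[keep])
  utils::write.csv(format_num(df), file.path(dir, "maps.csv"),
                   row.names = FALSE, quote = FALSE)
  write_mask_csv(maps$mask, file.path(dir, "mask.csv"))
  write_ti_csv(maps$ti_table, file.path(dir, "ti_table.csv"))
  meta <- maps$meta; meta$shape <- d
  jsonlite::write_json(serialize_meta(meta), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_maps
#' @export
read_maps <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  d <- as.integer(meta$shape); meta$shape <- NULL
  df <- utils::read.csv(file.path(dir, "maps.csv"))
  mk <- function(mode) array(vector(mode, 1)[NA], d)
  a_map <- mk("numeric"); t1_map <- mk("numeric"); sse_map <- mk("numeric")
  pol_map <- mk("integer"); conv_map <- mk("logical")
  idx <- cbind(df$phase_index + 1L, df$row + 1L, df$col + 1L)
  a_map[idx] <- df$a; t1_map[idx] <- df$t1_star_ms; sse_map[idx] <- df$sse
  pol_map[idx] <- df$polarity_k; conv_map[idx] <- df$converged
  structure(list(a_map = a_map, t1_star_map = t1_map, sse_map = sse_map,
                 polarity_map = pol_map, converged_map = conv_map,
                 mask = read_mask_csv(file.path(dir, "mask.csv")),
                 ti_table = read_ti_csv(file.path(dir, "ti_table.csv")),
                 meta = meta),
            class = "t1star_maps")
}

#' Write / read a binary mask as CSV
#'
#' Plain 0/1 matrix without headers, one image row per CSV line.
#'
#' @param mask Logical matrix.
#' @param path CSV path.
#' @return `write_mask_csv`: `path` invisibly; `read_mask_csv`: logical
#'   matrix.
#' @export
write_mask_csv <- function(mask, path) {
  stopifnot(is.logical(mask), is.matrix(mask))
  utils::write.table(mask * 1L, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_mask_csv
#' @export
read_mask_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  if (!all(m %in% c(0, 1))) stop("mask CSV must contain only 0/1")
  m == 1
}

#' Write / read a synthesized LGE stack as plain text
#'
#' `synth.csv` (long: `phase_index`, `row`, `col`, `value`, 0-based) plus
#' a `meta.json` sidecar recording `t_syn_ms`, output mode and shape.
#'
#' @param stack A `synth_lge_stack`.
#' @param dir Output directory.
#' @return `write_synth`: `dir` invisibly; `read_synth`: the object.
#' @export
write_synth <- function(stack, dir) {
  stopifnot(inherits(stack, "synth_lge_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(stack$data)
  grid <- expand.grid(phase_index = seq_len(d[1]) - 1L,
                      row = seq_len(d[2]) - 1L, col = seq_len(d[3]) - 1L)
  grid$value <- as.vector(stack$data)
  utils::write.csv(format_num(grid), file.path(dir, "synth.csv"),
                   row.names = FALSE, quote = FALSE)
  meta <- stack$meta
  meta$shape <- d; meta$t_syn_ms <- stack$t_syn_ms; meta$mode <- stack$mode
  jsonlite::write_json(serialize_meta(meta), file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_synth
#' @export
read_synth <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  d <- as.integer(meta$shape)
  df <- utils::read.csv(file.path(dir, "synth.csv"))
  arr <- array(NA_real_, d)
  arr[cbind(df$phase_index + 1L, df$row + 1L, df$col + 1L)] <- df$value
  t_syn <- meta$t_syn_ms; mode <- meta$mode
  meta$shape <- NULL
  structure(list(data = arr, t_syn_ms = t_syn, mode = mode, mask = NULL,
                 meta = meta),
            class = "synth_lge_stack")
}

#' Write a contrast report to CSV + JSON
#'
#' `report.csv` has one row per acquired phase (`phase_index`, `acnr` and,
#' if computed, `cnr`); `summary.json` carries the CoV summaries, phase
#' counts and `t_syn_ms`.
#'
#' @param report A [contrast_report()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "contrast_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  df <- data.frame(phase_index = seq_len(report$n_phases) - 1L,
                   acnr = report$per_phase_acnr)
  if (!is.null(report$phantom_cnr)) df$cnr <- report$phantom_cnr
  utils::write.csv(format_num(df), file.path(dir, "report.csv"),
                   row.names = FALSE, quote = FALSE)
  summ <- list(cov_acnr_percent = report$cov_acnr_percent,
               cov_cnr_percent = report$cov_cnr_percent,
               n_phases = report$n_phases,
               n_recon_phases = length(report$interpolated_acnr),
               t_syn_ms = report$t_syn_ms,
               interpolated_acnr = report$interpolated_acnr)
  jsonlite::write_json(summ, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
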