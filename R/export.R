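# Exporters: IMOD alignment files (.rawtlt/.tlt/.xf/.tltxf, newst.com,
# tilt.com, clean stack), Ctfplotter-style defocus files and RELION order
# list + STAR metadata, plus the small parsers used for round-trip checks.

fmt <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

# per-image 2x3 IMOD transforms (a11 a12 a21 a22 dx dy) from the solved
# model + pair shifts, feature-motion convention on centred coordinates
alignment_transforms <- function(model, shift_table, nominal_axis_deg,
                                 indices) {
  out <- matrix(0, length(indices), 6)
  for (r in seq_along(indices)) {
    i <- indices[r]
    phi <- deg2rad(model$rotation_deg[i])
    ps <- c(shift_table$dx[i], shift_table$dy[i])
    tv <- model$shift[i, ]
    A <- t(rot2(phi + deg2rad(nominal_axis_deg))) / model$scale
    b <- -(t(rot2(phi)) %*% (ps + tv)) / model$scale
    out[r, ] <- c(A[1, 1], A[1, 2], A[2, 1], A[2, 2], b[1], b[2])
  }
  out
}

#' Export IMOD-compatible alignment files
#'
#' Writes `<base>.rawtlt` (nominal angles), `<base>.tlt` (corrected
#' angles), `<base>.xf`/`<base>.tltxf` (per-image 2x3 transforms, IMOD
#' line convention `a11 a12 a21 a22 dx dy`, shifts in unbinned pixels),
#' `newst.com`/`tilt.com` command templates and, when any image was
#' deleted, `<base>_clean.mrc` with only the usable images.  All per-view
#' files are restricted to usable images.
#'
#' @param model an `alignment_model`.
#' @param series the (by-tilt) `tilt_series` with final usability flags;
#'   `extra$nominal_tilt_deg` may carry the uncorrected angles.
#' @param shift_table coarse `shift_table` from [align_pairs()].
#' @param out_dir output directory (created).
#' @param base file basename.
#' @return list of written paths (class `export_bundle`).
#' @export
export_imod <- function(model, series, shift_table, out_dir,
                        base = "series") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  use <- which(series$meta$usable)
  if (!length(use)) stop("cannot export a series with no usable images")
  p <- function(ext) file.path(out_dir, paste0(base, ext))
  nominal <- series$extra$nominal_tilt_deg %||% series$meta$tilt_angle_deg
  writeLines(fmt(nominal[use]), p(".rawtlt"))
  writeLines(fmt(series$meta$tilt_angle_deg[use]), p(".tlt"))
  tr <- alignment_transforms(model, shift_table,
                             series$nominal_tilt_axis_deg, use)
  xf_lines <- apply(tr, 1, function(v)
    paste(c(formatC(v[1:4], format = "f", digits = 7),
            formatC(v[5:6], format = "f", digits = 3)), collapse = "  "))
  writeLines(xf_lines, p(".xf"))
  writeLines(xf_lines, p(".tltxf"))
  clean_path <- NULL
  stack_name <- paste0(base, ".mrc")
  if (any(!series$meta$usable)) {
    clean_path <- file.path(out_dir, paste0(base, "_clean.mrc"))
    write_tilt_series(series, clean_path, include_unusable = FALSE)
    stack_name <- basename(clean_path)
  }
  d <- dim(series$images[[1]])
  newst <- c("$newstack -StandardInput",
             paste0("InputFile\t", stack_name),
             paste0("OutputFile\t", base, "_ali.mrc"),
             paste0("TransformFile\t", base, ".xf"),
             "BinByFactor\t1", "AdjustOrigin", "TaperAtFill\t1,0")
  writeLines(newst, file.path(out_dir, "newst.com"))
  tiltcom <- c("$tilt -StandardInput",
               paste0("InputProjections ", base, "_ali.mrc"),
               paste0("OutputFile ", base, "_rec.mrc"),
               paste0("TILTFILE ", base, ".tlt"),
               paste0("THICKNESS ", max(64, d[2] %/% 2)),
               "RADIAL 0.35 0.035", "MODE 2", "PERPENDICULAR")
  writeLines(tiltcom, file.path(out_dir, "tilt.com"))
  structure(list(rawtlt = p(".rawtlt"), tlt = p(".tlt"), xf = p(".xf"),
                 tltxf = p(".tltxf"),
                 newst_com = file.path(out_dir, "newst.com"),
                 tilt_com = file.path(out_dir, "tilt.com"),
                 clean_mrc = clean_path), class = "export_bundle")
}

#' Read an IMOD transform file
#' @param path `.xf`/`.tltxf` file.
#' @return n x 6 matrix (a11 a12 a21 a22 dx dy).
#' @export
read_xf <- function(path) {
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  stopifnot(ncol(m) == 6)
  m
}

#' Export a Ctfplotter-style defocus file
#'
#' One row per usable image: view range, tilt-angle range, the two
#' astigmatic defocus values in nanometres and the astigmatism angle; the
#' first row carries the format version flag (2) as a trailing column.
#'
#' @param ctf_fit a `ctf_series_fit`.
#' @param series the `tilt_series` the fit belongs to.
#' @param path output `.defocus` path.
#' @return `path`, invisibly.
#' @export
export_ctfplotter <- function(ctf_fit, series, path) {
  use <- which(series$meta$usable & !is.na(ctf_fit$defocus_um))
  ang <- series$meta$tilt_angle_deg
  lines <- vapply(seq_along(use), function(r) {
    i <- use[r]
    f_nm <- ctf_fit$defocus_um[i] * 1e3
    a_nm <- ctf_fit$astig_um * 1e3
    l <- paste(r, r, fmt(ang[i]), fmt(ang[i]),
               fmt(f_nm + a_nm, 1), fmt(f_nm - a_nm, 1),
               fmt(ctf_fit$astig_angle_deg, 2), sep = "\t")
    if (r == 1L) l <- paste(l, "2", sep = "\t")
    l
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Ctfplotter-style defocus file
#' @param path `.defocus` file.
#' @return data frame: view1, view2, tilt1, tilt2, defocus1_nm,
#'   defocus2_nm, astig_angle_deg.
#' @export
read_ctfplotter <- function(path) {
  rows <- strsplit(readLines(path), "\t")
  df <- do.call(rbind, lapply(rows, function(r)
    as.numeric(r[1:7])))
  df <- as.data.frame(df)
  names(df) <- c("view1", "view2", "tilt1", "tilt2", "defocus1_nm",
                 "defocus2_nm", "astig_angle_deg")
  df
}

#' Export RELION-compatible files
#'
#' Writes the per-position acquisition-order list (`<base>_order.csv`:
#' acquisition order, tilt angle, preserving the dose-symmetric sequence)
#' and a tilt-series STAR file with per-image alignment and defocus
#' metadata.
#'
#' @param series the processed `tilt_series`.
#' @param model an `alignment_model`.
#' @param ctf_fit a `ctf_series_fit` (or NULL to skip defocus columns).
#' @param out_dir output directory.
#' @param base basename.
#' @return list with `order_csv` and `star` paths.
#' @export
export_relion <- function(series, model, ctf_fit, out_dir,
                          base = "series") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  use <- which(series$meta$usable)
  ord <- order(series$meta$acquisition_index[use])
  rows <- use[ord]
  order_csv <- file.path(out_dir, paste0(base, "_order.csv"))
  write.csv(data.frame(order = seq_along(rows),
                       tilt_angle = series$meta$tilt_angle_deg[rows]),
            order_csv, row.names = FALSE, quote = FALSE)
  star <- file.path(out_dir, paste0(base, ".star"))
  f_um <- if (is.null(ctf_fit)) rep(NA_real_, n_images(series)) else
    ctf_fit$defocus_um
  a_um <- if (is.null(ctf_fit)) 0 else ctf_fit$astig_um
  t_dg <- if (is.null(ctf_fit)) 0 else ctf_fit$astig_angle_deg
  cols <- c("_rlnTomoTiltMovieIndex", "_rlnTomoNominalStageTiltAngle",
            "_rlnTomoNominalTiltAxisAngle", "_rlnTomoXShiftAngst",
            "_rlnTomoYShiftAngst", "_rlnDefocusU", "_rlnDefocusV",
            "_rlnDefocusAngle")
  body <- vapply(seq_along(rows), function(r) {
    i <- rows[r]
    du <- (f_um[i] + a_um) * 1e4   # Angstrom, RELION convention
    dv <- (f_um[i] - a_um) * 1e4
    paste(series$meta$acquisition_index[i],
          fmt(series$meta$tilt_angle_deg[i]),
          fmt(model$tilt_axis_deg),
          fmt(model$shift[i, 1] * series$pixel_size_A, 3),
          fmt(model$shift[i, 2] * series$pixel_size_A, 3),
          fmt(du, 1), fmt(dv, 1), fmt(t_dg), sep = "\t")
  }, character(1))
  writeLines(c(paste0("data_", base), "", "loop_",
               paste0(cols, " #", seq_along(cols)), body), star)
  list(order_csv = order_csv, star = star)
}

#' Minimal STAR file reader (single loop block)
#' @param path STAR file.
#' @return data frame with the loop columns.
#' @export
read_star <- function(path) {
  lines <- readLines(path)
  loop_at <- which(trimws(lines) == "loop_")[1]
  if (is.na(loop_at)) stop("no loop_ block in ", path)
  rest <- lines[(loop_at + 1):length(lines)]
  is_col <- grepl("^_", trimws(rest))
  n_col <- which(!is_col)[1] - 1
  cols <- sub("\\s+#\\d+$", "", trimws(rest[seq_len(n_col)]))
  body <- rest[(n_col + 1):length(rest)]
  body <- body[nzchar(trimws(body))]
  df <- do.call(rbind, strsplit(trimws(body), "\\s+"))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  names(df) <- cols
  for (j in seq_along(df)) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (!anyNA(v)) df[[j]] <- v
  }
  df
}
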