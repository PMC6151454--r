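#' Read an amide chemical-shift table
#'
#' Reads a delimited text file (comma or tab; auto-detected) whose
#' header names a residue-number column, an amide-proton (HN) shift
#' column and an amide-nitrogen (N) shift column. Rows with missing
#' values are dropped with a warning.
#'
#' @param path file path.
#' @param label `"free"` or `"bound"`.
#' @return data.frame of class `"shift_table"` with columns `resno`,
#'   `resid` (may be `NA`), `delta_HN`, `delta_N` (ppm).
#' @export
read_shift_table <- function(path, label = c("free", "bound")) {
  label <- match.arg(label)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  nm <- tolower(names(df))
  res_col <- which(grepl("res.*(no|num)|^residue$|^resno$|^res$", nm))[1L]
  hn_col <- which(grepl("hn|^h$|1h|proton", nm) & !grepl("^n", nm))[1L]
  n_col <- which(nm == "n" | grepl("^n15|15n|^delta_n$|nitrogen", nm))[1L]
  if (is.na(res_col) || is.na(hn_col) || is.na(n_col)) {
    stop("format error: could not identify residue/HN/N columns in ",
         paste(names(df), collapse = ","))
  }
  name_col <- which(grepl("name|resid|aa|type", nm) &
                      !(seq_along(nm) %in% c(res_col, hn_col, n_col)))[1L]
  out <- data.frame(
    resno = suppressWarnings(as.integer(df[[res_col]])),
    resid = if (is.na(name_col)) NA_character_
            else as.character(df[[name_col]]),
    delta_HN = suppressWarnings(as.numeric(df[[hn_col]])),
    delta_N = suppressWarnings(as.numeric(df[[n_col]])),
    stringsAsFactors = FALSE)
  bad <- is.na(out$resno) | is.na(out$delta_HN) | is.na(out$delta_N)
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing values dropped", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  if (anyDuplicated(out$resno)) stop("duplicate residue numbers")
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- c("shift_table", "data.frame")
  out
}

#' Write a shift table to CSV
#' @param table a `"shift_table"`.
#' @param path output path.
#' @export
write_shift_table <- function(table, path) {
  utils::write.table(table[, c("resno", "resid", "delta_HN", "delta_N")],
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalized chemical-shift perturbation per residue
#'
#' For every residue present in both tables, computes the normalized
#' amide perturbation
#' `delta_residue = sqrt(((dHN)^2 + (dN/5)^2) / 2)` where `dHN` and
#' `dN` are the bound-minus-free amide proton and nitrogen shift
#' differences (ppm); the 1/5 factor scales the nitrogen dimension to
#' the proton one. Residues exceeding 2x and 3x the mean perturbation
#' are flagged.
#'
#' @param free,bound `"shift_table"` objects sharing residue numbers.
#' @return `"csp_result"`: `records` (resno, d_HN, d_N,
#'   delta_residue, over_2x, over_3x), `mean_csp`, `threshold_2x`,
#'   `threshold_3x`, `n_residues`.
#' @export
compute_csp <- function(free, bound) {
  common <- intersect(free$resno, bound$resno)
  if (length(common) == 0L) stop("tables share no residues")
  common <- sort(common)
  f <- free[match(common, free$resno), ]
  b <- bound[match(common, bound$resno), ]
  d_HN <- b$delta_HN - f$delta_HN
  d_N <- b$delta_N - f$delta_N
  delta <- sqrt((d_HN^2 + (d_N / 5)^2) / 2)
  m <- mean(delta)
  rec <- data.frame(resno = common, d_HN = d_HN, d_N = d_N,
                    delta_residue = delta,
                    over_2x = delta > 2 * m, over_3x = delta > 3 * m)
  structure(list(records = rec, mean_csp = m,
                 threshold_2x = 2 * m, threshold_3x = 3 * m,
                 n_residues = length(common)),
            class = "csp_result")
}

#' @export
print.csp_result <- function(x, ...) {
  cat(sprintf("<csp_result: %d residues, mean %.3f ppm, %d over 3x mean>\n",
              x$n_residues, x$mean_csp, sum(x$records$over_3x)))
  invisible(x)
}

#' Contiguous perturbed regions above a mean-multiple threshold
#'
#' Returns maximal runs of consecutive residue numbers whose
#' perturbation exceeds `multiplier` times the mean. A gap of one
#' residue number is bridged when the intervening residue is absent
#' from the records (unassigned prolines and overlapped peaks are
#' routine in amide CSP maps); a residue that is present but below
#' threshold always breaks a run.
#'
#' @param csp a `"csp_result"` (or its `records` data.frame).
#' @param multiplier threshold as a multiple of the mean perturbation.
#' @param bridge_gaps bridge single missing-residue gaps? Default TRUE.
#' @return data.frame with columns `start`, `end` (author numbering);
#'   zero rows when nothing exceeds the threshold.
#' @export
perturbed_regions <- function(csp, multiplier = 3, bridge_gaps = TRUE) {
  rec <- if (inherits(csp, "csp_result")) csp$records else csp
  if (nrow(rec) == 0L) stop("no CSP records")
  if (multiplier <= 0) stop("multiplier must be positive")
  m <- if (inherits(csp, "csp_result")) csp$mean_csp else {
    mean(rec$delta_residue)
  }
  hot <- sort(rec$resno[rec$delta_residue > multiplier * m])
  if (length(hot) == 0L) return(data.frame(start = integer(),
                                           end = integer()))
  present <- rec$resno
  joins <- function(a, b) {
    if (b - a == 1L) return(TRUE)
    if (!bridge_gaps || b - a != 2L) return(FALSE)
    !((a + 1L) %in% present)  # bridge only across unassigned residues
  }
  starts <- hot[1L]
  ends <- hot[1L]
  for (r in hot[-1L]) {
    k <- length(ends)
    if (joins(ends[k], r)) ends[k] <- r
    else {
      starts <- c(starts, r)
      ends <- c(ends, r)
    }
  }
  data.frame(start = starts, end = ends)
}
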