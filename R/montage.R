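#' Contact layout of an implanted electrode array
#'
#' Describes the physical arrangement of contacts on one array: a strip or
#' depth electrode (a single row of contacts) or a subdural grid
#' (`n_rows x n_cols`, contact ids listed row-major).
#'
#' @param array_id Array identifier.
#' @param kind One of `"strip"`, `"depth"`, `"grid"`.
#' @param n_rows,n_cols Grid dimensions; strips and depths have `n_rows = 1`.
#' @param contact_ids Character vector of contact identifiers, row-major for
#'   grids. `NA` marks an excluded/missing contact position.
#' @return An object of class `contact_layout`.
#' @export
contact_layout <- function(array_id, kind, n_rows, n_cols, contact_ids) {
  kind <- match.arg(kind, c("strip", "depth", "grid"))
  if (kind != "grid" && n_rows != 1) {
    stop("layout '", array_id, "': ", kind, " arrays must have n_rows = 1")
  }
  if (n_rows * n_cols != length(contact_ids)) {
    stop("layout '", array_id, "': n_rows * n_cols = ", n_rows * n_cols,
         " but ", length(contact_ids), " contact ids supplied")
  }
  ids <- contact_ids[!is.na(contact_ids)]
  if (anyDuplicated(ids)) {
    stop("layout '", array_id, "': duplicate contact ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  structure(list(array_id = as.character(array_id), kind = kind,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 contact_ids = as.character(contact_ids)),
            class = "contact_layout")
}

#' Build the bipolar montage for a set of arrays
#'
#' Pairs every two spatially adjacent contacts along the same row or column.
#' A strip or depth array of `N` contacts yields `N - 1` bipolar electrodes;
#' an `i x j` grid yields `(i-1)*j + (j-1)*i`. Pairs are ordered
#' deterministically: row-wise pairs in row-major order first, then
#' column-wise pairs in column-major order. Pairs that touch a missing
#' (`NA`) contact are skipped with a warning. Neighbouring pairs share
#' contacts, so the derived signals are not all independent.
#'
#' @param layouts A `contact_layout` or list of them.
#' @param subject_id Subject identifier attached to every electrode.
#' @return Data frame with columns `electrode_id`, `contact_a`, `contact_b`,
#'   `array_id`, `kind`, `subject_id`.
#' @export
build_bipolar_montage <- function(layouts, subject_id = "S1") {
  if (inherits(layouts, "contact_layout")) layouts <- list(layouts)
  all_ids <- unlist(lapply(layouts, function(l) l$contact_ids))
  all_ids <- all_ids[!is.na(all_ids)]
  if (anyDuplicated(all_ids)) {
    stop("duplicate contact ids across layouts: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }
  rows <- lapply(layouts, function(l) {
    grid <- matrix(l$contact_ids, nrow = l$n_rows, ncol = l$n_cols,
                   byrow = TRUE)
    pairs <- list()
    # row-wise neighbours, row-major
    for (r in seq_len(l$n_rows)) {
      for (cc in seq_len(l$n_cols - 1)) {
        pairs[[length(pairs) + 1L]] <- c(grid[r, cc], grid[r, cc + 1])
      }
    }
    # column-wise neighbours, column-major
    if (l$n_rows > 1) {
      for (cc in seq_len(l$n_cols)) {
        for (r in seq_len(l$n_rows - 1)) {
          pairs[[length(pairs) + 1L]] <- c(grid[r, cc], grid[r + 1, cc])
        }
      }
    }
    if (length(pairs) == 0) {
      warning("layout '", l$array_id, "' has a single contact; no bipolar ",
              "pairs derived")
      return(NULL)
    }
    a <- vapply(pairs, `[`, "", 1L)
    b <- vapply(pairs, `[`, "", 2L)
    keep <- !is.na(a) & !is.na(b)
    if (any(!keep)) {
      warning("layout '", l$array_id, "': skipped ", sum(!keep),
              " pair(s) touching missing contacts")
    }
    if (!any(keep)) return(NULL)
    data.frame(contact_a = a[keep], contact_b = b[keep],
               array_id = l$array_id,
               kind = if (l$kind == "depth") "depth" else "subdural",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(contact_a = character(), contact_b = character(),
                      array_id = character(), kind = character())
  }
  out$electrode_id <- if (nrow(out)) paste0(out$contact_a, "-", out$contact_b) else character()
  out$subject_id <- rep(subject_id, nrow(out))
  rownames(out) <- NULL
  out[, c("electrode_id", "contact_a", "contact_b", "array_id", "kind",
          "subject_id")]
}

#' Derive bipolar signals by contact subtraction
#'
#' Each bipolar electrode's trace is `raw[contact_a, ] - raw[contact_b, ]`.
#'
#' @param raw Numeric matrix, contacts x samples, with contact ids as row
#'   names.
#' @param montage Montage data frame from [build_bipolar_montage()].
#' @return Numeric matrix, electrodes x samples, electrode ids as row names.
#' @export
subtract_bipolar <- function(raw, montage) {
  stopifnot(is.matrix(raw), !is.null(rownames(raw)))
  missing <- setdiff(unique(c(montage$contact_a, montage$contact_b)),
                     rownames(raw))
  if (length(missing)) {
    stop("contacts absent from the recording: ",
         paste(missing, collapse = ", "))
  }
  out <- raw[montage$contact_a, , drop = FALSE] -
    raw[montage$contact_b, , drop = FALSE]
  rownames(out) <- montage$electrode_id
  out
}

#' Event-locked epoch set
#'
#' Container for the per-electrode stacks of event-locked signal segments.
#'
#' @param data 3-way numeric array, electrode x trial x sample.
#' @param fs Sampling rate in Hz.
#' @param t0_offset Seconds from epoch start to word onset.
#' @param subject_id Subject identifier.
#' @param electrode_ids Electrode identifiers (length = dim 1).
#' @param trial_index Trial indices (length = dim 2).
#' @return An object of class `epoch_set`.
#' @export
epoch_set <- function(data, fs = 500, t0_offset = 0.7, subject_id = "S1",
                      electrode_ids = NULL, trial_index = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!all(is.finite(data))) stop("epoch_set: non-finite samples in data")
  if (is.null(electrode_ids)) electrode_ids <- paste0("E", seq_len(dim(data)[1]))
  if (is.null(trial_index)) trial_index <- seq_len(dim(data)[2])
  stopifnot(length(electrode_ids) == dim(data)[1],
            length(trial_index) == dim(data)[2])
  structure(list(data = data, fs = fs, t0_offset = t0_offset,
                 subject_id = subject_id,
                 electrode_ids = as.character(electrode_ids),
                 trial_index = trial_index),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> subject %s: %d electrodes x %d trials x %d samples @ %g Hz (onset %g s)\n",
    x$subject_id, d[1], d[2], d[3], x$fs, x$t0_offset))
  invisible(x)
}

#' Extract event-locked epochs
#'
#' Cuts one 3000 ms epoch per event from continuous 500 Hz signals: 700 ms
#' before word onset, 1600 ms of word presentation, 700 ms after. Windows are
#' half-open with 0-based sample indexing; the onset sample is
#' `floor(onset * fs)` and falls at offset 350 (0.7 s) within the epoch.
#' Events whose window leaves the recording are dropped with a warning.
#'
#' @param x Numeric matrix (electrodes x samples, electrode ids as row
#'   names) or a single numeric vector.
#' @param events Data frame with columns `trial_index` and `onset_s`
#'   (seconds on the recording clock), optionally `subject_id`.
#' @param fs Sampling rate; must be 500.
#' @param pre_s,post_s Epoch extent in seconds before/after onset.
#' @return An [epoch_set()].
#' @export
extract_epochs <- function(x, events, fs = 500, pre_s = 0.7, post_s = 2.3) {
  if (fs != 500) stop("extract_epochs expects fs = 500, got ", fs)
  if (!is.matrix(x)) {
    x <- matrix(x, nrow = 1, dimnames = list("E1", NULL))
  }
  stopifnot(all(c("trial_index", "onset_s") %in% names(events)))
  if (anyDuplicated(events$trial_index)) {
    stop("duplicate trial_index values in the event table")
  }
  if (is.unsorted(events$onset_s, strictly = TRUE)) {
    stop("event onsets must be strictly increasing")
  }
  n <- ncol(x)
  n_pre <- round(pre_s * fs); n_post <- round(post_s * fs)
  len <- n_pre + n_post
  # 0-based; the 1e-6 guard keeps sample-aligned onsets stable under
  # floating-point representation of onset_s
  onset_sample <- floor(events$onset_s * fs + 1e-6)
  start <- onset_sample - n_pre
  ok <- start >= 0 & (start + len) <= n
  if (any(!ok)) {
    warning(sum(!ok), " event(s) dropped: epoch window outside the recording")
  }
  if (!any(ok)) stop("no usable trials: every epoch window is out of bounds")
  start <- start[ok]
  dat <- array(0, c(nrow(x), sum(ok), len))
  for (k in seq_along(start)) {
    dat[, k, ] <- x[, (start[k] + 1):(start[k] + len), drop = FALSE]
  }
  subj <- if ("subject_id" %in% names(events)) as.character(events$subject_id[1]) else "S1"
  epoch_set(dat, fs = fs, t0_offset = pre_s, subject_id = subj,
            electrode_ids = rownames(x), trial_index = events$trial_index[ok])
}

#' Read an event table
#'
#' Tab-separated file with header columns `subject_id`, `trial_index`,
#' `onset_s` and optionally `word`.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_events <- function(path) {
  ev <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_index", "onset_s")
  if (!all(need %in% names(ev))) {
    stop("event table must have columns ", paste(need, collapse = ", "))
  }
  ev
}

#' Read contact layouts
#'
#' Tab-separated file with columns `array_id`, `kind`, `n_rows`, `n_cols`,
#' `contact_ids` (semicolon-joined).
#'
#' @param path File path.
#' @return List of [contact_layout()] objects.
#' @export
read_layouts <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    ids <- strsplit(tab$contact_ids[i], ";", fixed = TRUE)[[1]]
    ids[ids == "" | ids == "NA"] <- NA
    contact_layout(tab$array_id[i], tab$kind[i], tab$n_rows[i],
                   tab$n_cols[i], ids)
  })
}

#' Read a raw signal matrix
#'
#' Tab-separated file: first column `contact_id`, remaining columns samples.
#'
#' @param path File path.
#' @return Numeric matrix, contacts x samples, contact ids as row names.
#' @export
read_signals <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "double"
  m
}
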