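# Dataset containers, WFDB-compatible I/O, preprocessing, splitting, and the
# non-IID multicenter partitioning procedure.

#' Construct an ECG record
#'
#' @param waveform numeric matrix, leads x samples, in mV
#' @param sampling_rate sampling frequency in Hz
#' @param age age in years (integer)
#' @param sex `"male"` or `"female"`
#' @param label 0 (no arrhythmia) or 1 (arrhythmia)
#' @param record_id opaque record identifier
#' @param site_id opaque site identifier
#' @return an object of class `ecg_record`
#' @export
ecg_record <- function(waveform, sampling_rate, age, sex, label,
                       record_id, site_id = "") {
  stopifnot(is.matrix(waveform), sex %in% c("male", "female"),
            label %in% c(0L, 1L), age >= 0)
  structure(list(waveform = waveform, sampling_rate = sampling_rate,
                 age = as.integer(age), sex = sex, label = as.integer(label),
                 record_id = as.character(record_id),
                 site_id = as.character(site_id)),
            class = "ecg_record")
}

#' Construct a site dataset
#'
#' @param records list of [ecg_record()] objects
#' @param site_id opaque site identifier
#' @param partitions optional list of disjoint index vectors `train`, `val`,
#'   `test` whose union covers all records
#' @return an object of class `site_dataset` with `size_n = length(records)`
#' @export
site_dataset <- function(records, site_id = "", partitions = NULL) {
  if (!is.null(partitions)) {
    idx <- sort(unlist(partitions, use.names = FALSE))
    stopifnot(identical(as.integer(idx), seq_along(records)),
              !anyDuplicated(unlist(partitions)))
  }
  structure(list(records = records, site_id = as.character(site_id),
                 partitions = partitions, size_n = length(records)),
            class = "site_dataset")
}

#' @export
print.site_dataset <- function(x, ...) {
  cat("site_dataset", x$site_id, "with", x$size_n, "records")
  if (!is.null(x$partitions))
    cat(" (train/val/test =",
        paste(lengths(x$partitions), collapse = "/"), ")")
  cat("\n")
  invisible(x)
}

#' Records of one partition of a split site dataset
#'
#' @param dataset a split [site_dataset()]
#' @param part `"train"`, `"val"`, or `"test"`
#' @return list of `ecg_record`s
#' @export
partition_records <- function(dataset, part) {
  stopifnot(!is.null(dataset$partitions))
  dataset$records[dataset$partitions[[part]]]
}

## ---- WFDB-compatible I/O --------------------------------------------------
# Minimal reader/writer for WFDB header/signal pairs (format 16: 16-bit
# little-endian integers, sample-interleaved across signals). Covers the
# subset of the header specification that record-per-file 12-lead exports
# use. Demographics ride in a CSV with columns record_id, age, sex, label.

#' Write a site dataset as WFDB header/signal pairs plus a demographics CSV
#'
#' @param dataset a [site_dataset()]
#' @param path output directory (created if missing)
#' @param adc_gain integer units per mV (default 1000)
#' @return invisibly, the paths written
#' @export
write_wfdb_dataset <- function(dataset, path, adc_gain = 1000) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  demo <- data.frame(record_id = character(0), age = integer(0),
                     sex = character(0), label = integer(0))
  for (rec in dataset$records) {
    C <- nrow(rec$waveform); L <- ncol(rec$waveform)
    base <- rec$record_id
    hea <- c(sprintf("%s %d %g %d", base, C, rec$sampling_rate, L),
             sprintf("%s.dat 16 %g 16 0 0 0 0 lead%d", base, adc_gain,
                     seq_len(C)))
    writeLines(hea, file.path(path, paste0(base, ".hea")))
    dig <- round(rec$waveform * adc_gain)
    dig <- pmax(pmin(dig, 32767), -32768)
    con <- file(file.path(path, paste0(base, ".dat")), "wb")
    writeBin(as.integer(dig), con, size = 2, endian = "little")
    close(con)
    demo <- rbind(demo, data.frame(record_id = base, age = rec$age,
                                   sex = rec$sex, label = rec$label))
  }
  utils::write.csv(demo, file.path(path, "demographics.csv"),
                   row.names = FALSE)
  invisible(path)
}

read_wfdb_record <- function(hea_path) {
  lines <- readLines(hea_path, warn = FALSE)
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  base <- top[1]; nsig <- as.integer(top[2])
  fs <- as.numeric(top[3]); nsamp <- as.integer(top[4])
  if (is.na(nsig) || is.na(fs) || is.na(nsamp) || length(lines) < 1 + nsig)
    stop("malformed header: ", hea_path)
  sig <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  fmt <- sig[2]
  if (fmt != "16") stop("unsupported signal format ", fmt, " in ", hea_path)
  gain <- as.numeric(sig[3])
  if (!is.finite(gain) || gain == 0) gain <- 200 # WFDB default gain
  dat_path <- file.path(dirname(hea_path), sig[1])
  con <- file(dat_path, "rb")
  raw <- readBin(con, integer(), n = nsig * nsamp, size = 2,
                 endian = "little", signed = TRUE)
  close(con)
  if (length(raw) != nsig * nsamp) stop("truncated signal file: ", dat_path)
  wave <- matrix(raw, nrow = nsig) / gain # stored sample-interleaved
  list(record_id = base, waveform = wave, sampling_rate = fs)
}

#' Read a directory of WFDB records with a demographics table
#'
#' Records whose demographics row is missing or incomplete (age, sex, or
#' label absent) are dropped and counted; unreadable headers are skipped
#' with a warning.
#'
#' @param path directory containing `.hea`/`.dat` pairs
#' @param demographics path to a CSV with columns `record_id`, `age`,
#'   `sex`, `label`; defaults to `demographics.csv` inside `path`
#' @param site_id site identifier attached to all records
#' @return a [site_dataset()]; attribute `dropped` counts removed records
#' @export
read_wfdb_dataset <- function(path,
                              demographics = file.path(path, "demographics.csv"),
                              site_id = basename(path)) {
  heas <- sort(list.files(path, pattern = "\\.hea$", full.names = TRUE))
  if (length(heas) == 0) stop("no WFDB headers found in ", path)
  demo <- utils::read.csv(demographics, stringsAsFactors = FALSE)
  stopifnot(all(c("record_id", "age", "sex", "label") %in% names(demo)))
  records <- list(); dropped <- 0L
  for (h in heas) {
    sig <- tryCatch(read_wfdb_record(h), error = function(e) {
      warning("skipping unreadable record ", basename(h), ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(sig)) next
    row <- demo[demo$record_id == sig$record_id, , drop = FALSE]
    if (nrow(row) != 1 || is.na(row$age) || is.na(row$label) ||
        !(row$sex %in% c("male", "female"))) {
      dropped <- dropped + 1L
      next
    }
    records[[length(records) + 1L]] <-
      ecg_record(sig$waveform, sig$sampling_rate, row$age, row$sex,
                 row$label, sig$record_id, site_id)
  }
  if (length(records) == 0) stop("no usable records in ", path)
  out <- site_dataset(records, site_id)
  attr(out, "dropped") <- dropped
  out
}

## ---- preprocessing --------------------------------------------------------

#' Filter records by age (inclusive bounds)
#'
#' Keeps exactly the records with `min_age <= age <= max_age`, preserving
#' input order. The defaults retain adult records up to age 100.
#'
#' @param records list of [ecg_record()] objects
#' @param min_age,max_age inclusive bounds in years
#' @return filtered list of records
#' @export
filter_by_age <- function(records, min_age = 18, max_age = 100) {
  if (min_age > max_age) stop("min_age must not exceed max_age")
  keep <- vapply(records, function(r) r$age >= min_age && r$age <= max_age,
                 logical(1))
  records[keep]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Filters each lead independently with a forward-backward (zero-phase)
#' application of an order-`order` Butterworth bandpass. The defaults
#' (0.5-40 Hz, order 5) remove baseline drift and mains interference while
#' passing the diagnostic ECG band.
#'
#' @param waveform leads x samples matrix
#' @param low,high band edges in Hz, `0 < low < high < fs/2`
#' @param order filter order (default 5)
#' @param fs sampling frequency in Hz
#' @return filtered matrix of the same shape
#' @export
bandpass_filter <- function(waveform, low = 0.5, high = 40, order = 5,
                            fs = 500) {
  if (!(low > 0 && low < high)) stop("need 0 < low < high")
  if (high >= fs / 2) stop("high band edge must be below the Nyquist frequency")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  L <- ncol(waveform)
  # odd-reflection padding lets the low corner's slow transient settle
  # outside the record before the forward-backward pass
  npad <- min(L - 1L, ceiling(3 * fs / low))
  t(apply(waveform, 1, function(ch) {
    head_pad <- 2 * ch[1] - ch[(npad + 1L):2L]
    tail_pad <- 2 * ch[L] - ch[(L - 1L):(L - npad)]
    padded <- c(head_pad, ch, tail_pad)
    signal::filtfilt(bf, padded)[(npad + 1L):(npad + L)]
  }))
}

#' Scale a record to the range [-1, 1]
#'
#' Affine map of the whole record so the record-wide minimum maps to -1 and
#' the maximum to +1; relative inter-lead amplitudes are preserved. A
#' constant record maps to all zeros. With `per_lead = TRUE` each lead is
#' scaled independently instead.
#'
#' @param waveform leads x samples matrix
#' @param per_lead scale each lead separately (default FALSE)
#' @return scaled matrix
#' @export
minmax_scale <- function(waveform, per_lead = FALSE) {
  scale1 <- function(x) {
    lo <- min(x); hi <- max(x)
    if (hi == lo) return(x * 0)
    2 * (x - lo) / (hi - lo) - 1
  }
  if (per_lead) t(apply(waveform, 1, scale1)) else scale1(waveform)
}

#' Apply the standard preprocessing to every record of a site
#'
#' Age filter, zero-phase Butterworth bandpass, then per-record min-max
#' scaling to `[-1, 1]` (filter first, then scale).
#'
#' @param dataset a [site_dataset()]
#' @param min_age,max_age inclusive age bounds
#' @param low,high,order bandpass settings (see [bandpass_filter()])
#' @return preprocessed [site_dataset()] (partitions are cleared)
#' @export
preprocess_site <- function(dataset, min_age = 18, max_age = 100,
                            low = 0.5, high = 40, order = 5) {
  recs <- filter_by_age(dataset$records, min_age, max_age)
  recs <- lapply(recs, function(r) {
    r$waveform <- minmax_scale(
      bandpass_filter(r$waveform, low, high, order, r$sampling_rate))
    r
  })
  site_dataset(recs, dataset$site_id)
}

## ---- splitting ------------------------------------------------------------

#' Randomly split a site dataset into train/validation/test partitions
#'
#' Non-train partitions receive `floor(n * ratio)` records; the remainder
#' goes to the training partition. Deterministic given `seed`.
#'
#' @param dataset a [site_dataset()]
#' @param ratios length-3 positive vector `(train, val, test)`, default 8:1:1
#' @param seed integer seed
#' @param stratify split within each label group (keeps both classes in
#'   every partition when group sizes allow); default FALSE
#' @return the dataset with a `partitions` field
#' @export
split_dataset <- function(dataset, ratios = c(8, 1, 1), seed = 0L,
                          stratify = FALSE) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  n <- dataset$size_n
  if (n < 3) stop("need at least 3 records to split")
  ratios <- ratios / sum(ratios)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, paste0("split-", dataset$site_id)))
  split_idx <- function(idx, min_one = FALSE) {
    m <- length(idx)
    m_val <- floor(m * ratios[2])
    m_test <- floor(m * ratios[3])
    # stratified groups of >= 3 records put at least one in every partition,
    # so both classes stay represented in validation and test metrics
    if (min_one && m >= 3) {
      m_val <- max(1L, m_val)
      m_test <- max(1L, m_test)
    }
    m_train <- m - m_val - m_test
    perm <- idx[sample.int(m)]
    list(train = perm[seq_len(m_train)],
         val = perm[m_train + seq_len(m_val)],
         test = perm[m_train + m_val + seq_len(m_test)])
  }
  if (stratify) {
    labels <- vapply(dataset$records, function(r) r$label, integer(1))
    parts <- lapply(sort(unique(labels)), function(l)
      split_idx(which(labels == l), min_one = TRUE))
    merged <- list(train = integer(0), val = integer(0), test = integer(0))
    for (p in parts) for (nm in names(merged))
      merged[[nm]] <- c(merged[[nm]], p[[nm]])
    parts <- merged
  } else {
    parts <- split_idx(seq_len(n))
  }
  if (any(lengths(parts) < 1))
    stop("split would leave an empty partition (n = ", n, ")")
  dataset$partitions <- lapply(parts, sort)
  dataset
}

## ---- non-IID multicenter partitioning -------------------------------------

#' Partition one dataset into four demographically non-IID sites
#'
#' Implements the four-group/ten-subgroup exchange procedure: records are
#' divided into four groups by age (below / at-or-above `age_cut`) and sex;
#' each group is randomly subdivided into `n_subgroups` near-equal
#' subgroups; each group donates `n_transfer` randomly chosen subgroups, one
#' to each of the other three groups (matched in fixed group order). The
#' four resulting sites partition the input exactly and each contains
#' records from all four demographic groups.
#'
#' @param dataset a [site_dataset()]
#' @param age_cut age threshold in years (default 60)
#' @param n_subgroups subgroups per demographic group (default 10)
#' @param n_transfer donated subgroups per group (default 3; must equal the
#'   number of other groups)
#' @param seed integer seed
#' @return list of four [site_dataset()] objects
#' @export
generate_noniid_sites <- function(dataset, age_cut = 60, n_subgroups = 10,
                                  n_transfer = 3, seed = 0L) {
  stopifnot(n_subgroups > n_transfer, n_transfer == 3)
  recs <- dataset$records
  grp <- vapply(recs, function(r) {
    1L + 2L * as.integer(r$age >= age_cut) + as.integer(r$sex == "male")
  }, integer(1))
  group_names <- c("age<cut/female", "age<cut/male",
                   "age>=cut/female", "age>=cut/male")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "noniid"))
  subgroups <- vector("list", 4) # per group: list of index vectors
  for (g in 1:4) {
    idx <- which(grp == g)
    if (length(idx) < n_subgroups)
      stop("group ", group_names[g], " has only ", length(idx),
           " records; cannot form ", n_subgroups, " subgroups")
    idx <- sample(idx)
    # near-equal contiguous chunks of the shuffled indices
    sizes <- rep(length(idx) %/% n_subgroups, n_subgroups)
    extra <- length(idx) %% n_subgroups
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    subgroups[[g]] <- split(idx, rep(seq_len(n_subgroups), sizes))
  }
  site_members <- lapply(1:4, function(g) integer(0))
  for (g in 1:4) {
    donated <- sample(n_subgroups, n_transfer)
    recipients <- setdiff(1:4, g) # fixed group order
    for (j in seq_len(n_transfer)) {
      site_members[[recipients[j]]] <-
        c(site_members[[recipients[j]]], subgroups[[g]][[donated[j]]])
    }
    kept <- setdiff(seq_len(n_subgroups), donated)
    site_members[[g]] <- c(site_members[[g]],
                           unlist(subgroups[[g]][kept], use.names = FALSE))
  }
  lapply(1:4, function(g) {
    members <- sort(site_members[[g]])
    rs <- recs[members]
    rs <- lapply(rs, function(r) { r$site_id <- paste0("site", g); r })
    site_dataset(rs, paste0("site", g))
  })
}
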