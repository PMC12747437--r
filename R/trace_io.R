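#' Read a chromatin-tracing trace table
#'
#' Two on-disk dialects are supported, both plain text with `#` comment lines:
#'
#' * `fofct_csv` — FOF-CT-style CSV with mandatory columns `Trace_ID`,
#'   `Chrom`, `Chrom_Start`, `Chrom_End`, `X`, `Y`, `Z` (coordinates in nm)
#'   and optional `Cell_ID`, `Condition`, `Burst_State`, `Locus_Role`.
#' * `simple_tsv` — columns `trace_id`, `locus_index`, `x_nm`, `y_nm`,
#'   `z_nm`, optional `role`, `burst_state`; optional `#locus` comment lines
#'   (written by [write_traces()]) carry genomic intervals and roles.
#'
#' Trace identity is the (cell, allele, condition) triple: `Cell_ID` x
#' `Trace_ID` x `Condition` for FOF-CT, `trace_id` for the TSV dialect. Loci
#' are ordered by genomic start. Cells whose coordinates do not parse (blank
#' or non-numeric) become missing spots and are counted in the parse report
#' attached as `attr(ts, "parse_report")`.
#'
#' @param path input file.
#' @param dialect `"fofct_csv"` or `"simple_tsv"`.
#' @return a [trace_set()] with a `parse_report` attribute
#'   (`rows_total`, `rows_clean`, `rows_with_missing_coords`,
#'   `bad_coord_cells`; `rows_clean + rows_with_missing_coords == rows_total`).
#' @seealso [write_traces()]
#' @export
read_traces <- function(path, dialect = c("fofct_csv", "simple_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
         fofct_csv = read_fofct(path),
         simple_tsv = read_simple_tsv(path))
}

#' Write a chromatin-tracing trace table
#'
#' Writes every (trace, locus) cell, localized or not, so that
#' `read_traces(write_traces(ts, f, d), d)` reproduces `ts` exactly (at the
#' chosen coordinate precision). Missing spots are written as empty fields.
#' Only 3-dimensional trace sets can be serialized.
#'
#' @param ts a `TraceSet` with `n_dims(ts) == 3`.
#' @param path output file.
#' @param dialect `"fofct_csv"` or `"simple_tsv"`.
#' @param digits decimal places of nm kept for coordinates (default 3).
#' @return `path`, invisibly.
#' @export
write_traces <- function(ts, path, dialect = c("fofct_csv", "simple_tsv"),
                         digits = 3) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(ts, "TraceSet"))
  if (n_dims(ts) != 3)
    stop("trace tables are 3D on disk; got D = ", n_dims(ts))
  switch(dialect,
         fofct_csv = write_fofct(ts, path, digits),
         simple_tsv = write_simple_tsv(ts, path, digits))
  invisible(path)
}

fmt_coord <- function(x, digits) ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))

num_or_na <- function(x) suppressWarnings(as.numeric(x))

# shared assembly: rows -> TraceSet + parse report
build_trace_set <- function(trace_key, locus_key, xyz, locus_df, meta_by_trace) {
  bad_cells <- sum(is.na(xyz))
  rows_bad <- sum(apply(is.na(xyz), 1, any))

  lk <- unique(locus_key)
  lmap <- setNames(seq_along(lk), lk)
  lidx <- lmap[locus_key]
  tk <- unique(trace_key)
  tmap <- setNames(seq_along(tk), tk)
  tidx <- tmap[trace_key]

  dup <- duplicated(cbind(tidx, lidx))
  if (any(dup)) {
    i <- which(dup)[1]
    stop(sprintf("duplicate (trace, locus) row: trace '%s', locus '%s'",
                 trace_key[i], locus_key[i]))
  }

  N <- length(tk); L <- length(lk)
  pos <- array(NA_real_, c(N, L, 3))
  for (d in 1:3) pos[cbind(tidx, lidx, d)] <- xyz[, d]

  lt <- locus_df[match(lk, locus_key), , drop = FALSE]
  rp <- derive_repeat_pairs(lt)

  ts <- trace_set(pos, locus_table = lt,
                  trace_meta = meta_by_trace[match(tk, trace_key), , drop = FALSE],
                  repeat_pairs = rp)
  attr(ts, "parse_report") <- list(
    rows_total = nrow(xyz),
    rows_clean = nrow(xyz) - rows_bad,
    rows_with_missing_coords = rows_bad,
    bad_coord_cells = bad_cells
  )
  ts
}

# pair each repeat locus with the initial locus covering the same interval
derive_repeat_pairs <- function(lt) {
  reps <- which(lt$role == "repeat")
  if (!length(reps))
    return(data.frame(initial_locus = integer(), repeat_locus = integer()))
  key <- paste(lt$chrom, lt$start, lt$end)
  ini <- which(lt$role == "initial")
  m <- match(key[reps], key[ini])
  keep <- !is.na(m)
  data.frame(initial_locus = ini[m[keep]], repeat_locus = reps[keep])
}

read_fofct <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(body) < 2) stop("no data rows in ", path)
  df <- read.csv(text = paste(body, collapse = "\n"),
                 colClasses = "character", check.names = FALSE)
  need <- c("Trace_ID", "Chrom", "Chrom_Start", "Chrom_End", "X", "Y", "Z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("fofct_csv: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))

  xyz <- cbind(num_or_na(df$X), num_or_na(df$Y), num_or_na(df$Z))
  role <- if ("Locus_Role" %in% names(df)) df$Locus_Role else rep("initial", nrow(df))
  cell <- if ("Cell_ID" %in% names(df)) df$Cell_ID else rep("cell1", nrow(df))
  cond <- if ("Condition" %in% names(df)) df$Condition else rep("default", nrow(df))
  burst <- if ("Burst_State" %in% names(df)) df$Burst_State else rep("none", nrow(df))

  locus_df <- data.frame(chrom = df$Chrom,
                         start = num_or_na(df$Chrom_Start),
                         end = num_or_na(df$Chrom_End),
                         role = role, stringsAsFactors = FALSE)
  locus_key <- paste(locus_df$chrom, locus_df$start, locus_df$end, locus_df$role,
                     sep = "|")
  trace_key <- paste(cell, df$Trace_ID, cond, sep = "|")
  meta <- data.frame(trace_id = df$Trace_ID, cell = cell, allele = df$Trace_ID,
                     condition = cond, burst_state = burst,
                     stringsAsFactors = FALSE)
  build_trace_set(trace_key, locus_key, xyz, locus_df, meta)
}

write_fofct <- function(ts, path, digits) {
  N <- n_traces(ts); L <- n_loci(ts)
  lt <- ts$locus_table; tm <- ts$trace_meta
  i <- rep(seq_len(N), each = L)
  l <- rep(seq_len(L), times = N)
  df <- data.frame(
    Trace_ID = tm$trace_id[i],
    Cell_ID = tm$cell[i],
    Condition = tm$condition[i],
    Burst_State = tm$burst_state[i],
    Chrom = lt$chrom[l],
    Chrom_Start = format(lt$start[l], scientific = FALSE, trim = TRUE),
    Chrom_End = format(lt$end[l], scientific = FALSE, trim = TRUE),
    X = fmt_coord(ts$positions[cbind(i, l, 1)], digits),
    Y = fmt_coord(ts$positions[cbind(i, l, 2)], digits),
    Z = fmt_coord(ts$positions[cbind(i, l, 3)], digits),
    stringsAsFactors = FALSE
  )
  if (any(lt$role == "repeat")) df$Locus_Role <- lt$role[l]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# FOF-CT-style chromatin trace table; coordinates in nm", con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
}

read_simple_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_comment <- startsWith(trimws(lines), "#")
  locus_lines <- lines[is_comment & startsWith(trimws(lines), "#locus")]
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) < 2) stop("no data rows in ", path)
  df <- read.delim(text = paste(body, collapse = "\n"),
                   colClasses = "character", check.names = FALSE)
  need <- c("trace_id", "locus_index", "x_nm", "y_nm", "z_nm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("simple_tsv: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))

  xyz <- cbind(num_or_na(df$x_nm), num_or_na(df$y_nm), num_or_na(df$z_nm))
  idx <- as.integer(df$locus_index)
  if (any(is.na(idx))) stop("simple_tsv: unparseable locus_index")
  role <- if ("role" %in% names(df)) df$role else rep("initial", nrow(df))
  burst <- if ("burst_state" %in% names(df)) df$burst_state else rep("none", nrow(df))

  # locus metadata either from '#locus' header lines or synthesized at 1 kb
  if (length(locus_lines)) {
    parts <- strsplit(sub("^#locus\\s+", "", trimws(locus_lines)), "\t")
    ml <- do.call(rbind, lapply(parts, function(p) {
      data.frame(idx = as.integer(p[1]), chrom = p[2],
                 start = as.numeric(p[3]), end = as.numeric(p[4]),
                 role = p[5], stringsAsFactors = FALSE)
    }))
    ml <- ml[order(ml$idx), ]
    locus_df <- data.frame(chrom = ml$chrom[idx], start = ml$start[idx],
                           end = ml$end[idx], role = ml$role[idx],
                           stringsAsFactors = FALSE)
  } else {
    locus_df <- data.frame(chrom = "chr1", start = (idx - 1) * 1000,
                           end = idx * 1000, role = role,
                           stringsAsFactors = FALSE)
  }
  locus_key <- sprintf("locus_%06d", idx)
  meta <- data.frame(trace_id = df$trace_id, cell = df$trace_id, allele = "1",
                     condition = "default", burst_state = burst,
                     stringsAsFactors = FALSE)
  build_trace_set(df$trace_id, locus_key, xyz, locus_df, meta)
}

write_simple_tsv <- function(ts, path, digits) {
  N <- n_traces(ts); L <- n_loci(ts)
  lt <- ts$locus_table; tm <- ts$trace_meta
  i <- rep(seq_len(N), each = L)
  l <- rep(seq_len(L), times = N)
  df <- data.frame(
    trace_id = tm$trace_id[i],
    locus_index = l,
    x_nm = fmt_coord(ts$positions[cbind(i, l, 1)], digits),
    y_nm = fmt_coord(ts$positions[cbind(i, l, 2)], digits),
    z_nm = fmt_coord(ts$positions[cbind(i, l, 3)], digits),
    role = lt$role[l],
    burst_state = tm$burst_state[i],
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# simple_tsv chromatin trace table; coordinates in nm", con)
  writeLines(sprintf("#locus %d\t%s\t%s\t%s\t%s", seq_len(L), lt$chrom,
                     format(lt$start, scientific = FALSE, trim = TRUE),
                     format(lt$end, scientific = FALSE, trim = TRUE), lt$role),
             con)
  suppressWarnings(write.table(df, con, sep = "\t", row.names = FALSE,
                               quote = FALSE))
}
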