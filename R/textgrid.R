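# Praat TextGrid reader/writer. Both text dialects ("long" with key = value
# lines, "short" with bare values) are supported, in UTF-8 or UTF-16 (Praat
# writes UTF-16 with a BOM by default). Only interval tiers carry elements;
# point tiers are rejected when selected.

tg_read_lines <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  raw <- readBin(con, "raw", file.info(path)$size)
  enc <- "UTF-8"
  if (length(raw) >= 2 && raw[1] == as.raw(0xFE) && raw[2] == as.raw(0xFF)) {
    enc <- "UTF-16BE"; raw <- raw[-(1:2)]
  } else if (length(raw) >= 2 && raw[1] == as.raw(0xFF) && raw[2] == as.raw(0xFE)) {
    enc <- "UTF-16LE"; raw <- raw[-(1:2)]
  } else if (length(raw) >= 3 && identical(raw[1:3], as.raw(c(0xEF, 0xBB, 0xBF)))) {
    raw <- raw[-(1:3)]
  }
  txt <- if (startsWith(enc, "UTF-16")) {
    iconv(list(raw), from = enc, to = "UTF-8")
  } else {
    rawToChar(raw)
  }
  strsplit(gsub("\r\n?", "\n", txt), "\n", fixed = TRUE)[[1]]
}

tg_unquote <- function(x) {
  x <- sub('^\\s*"', "", x)
  x <- sub('"\\s*$', "", x)
  gsub('""', '"', x)  # Praat escapes embedded quotes by doubling
}

# Tokenise the body shared by both dialects: numbers, quoted strings and
# flags, in file order. Long-format decoration (keys, brackets) is stripped.
tg_tokens <- function(lines) {
  lines <- lines[!grepl("^\\s*$", lines)]
  lines <- lines[!grepl("^\\s*(item|intervals|points)\\s*\\[", lines)]
  keyre <- "^\\s*[A-Za-z][A-Za-z ]*[:=]\\s*"   # 'xmin = ', 'intervals: size = '
  lines <- sub(keyre, "", lines)
  lines <- sub(keyre, "", lines)
  trimws(lines)
}

parse_textgrid <- function(path) {
  lines <- tg_read_lines(path)
  if (!any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))]))) {
    stop("not a Praat TextGrid text file: ", path)
  }
  toks <- tg_tokens(lines[-(1:2)])  # drop File type / Object class
  toks <- toks[toks != ""]
  i <- 1L
  nxt <- function() { v <- toks[i]; i <<- i + 1L; v }
  num <- function() as.numeric(nxt())
  str <- function() tg_unquote(nxt())
  num(); num()                       # global xmin, xmax
  has_tiers <- nxt()                 # <exists> / "exists" flag (any spelling)
  if (!grepl("exists", has_tiers) && !grepl("^1$|TRUE", has_tiers)) {
    stop("TextGrid declares no tiers: ", path)
  }
  ntier <- num()
  tiers <- vector("list", ntier)
  for (t in seq_len(ntier)) {
    klass <- str()
    name <- str()
    num(); num()                     # tier xmin, xmax
    n <- num()
    if (identical(klass, "IntervalTier")) {
      xmin <- xmax <- numeric(n); lab <- character(n)
      for (k in seq_len(n)) {
        xmin[k] <- num(); xmax[k] <- num(); lab[k] <- str()
      }
      tiers[[t]] <- list(class = klass, name = name,
                         xmin = xmin, xmax = xmax, label = lab)
    } else {
      tm <- numeric(n); lab <- character(n)
      for (k in seq_len(n)) { tm[k] <- num(); lab[k] <- str() }
      tiers[[t]] <- list(class = klass, name = name, time = tm, label = lab)
    }
  }
  tiers
}

#' Read an interval tier of a Praat TextGrid into an annotation set
#'
#' Both the long and the short text dialect are accepted, in UTF-8 or UTF-16.
#' Every non-empty interval on the requested tier becomes one element record;
#' intervals with an empty label are silences and are skipped.
#'
#' @param path path to a `.TextGrid` file.
#' @param tier name of the interval tier holding the elements. There is no
#'   universal tier naming convention across annotation projects, so the name
#'   must be given explicitly; the error for a missing tier lists the tiers
#'   present.
#' @param individual identifier of the vocalising individual (TextGrids carry
#'   no individual field).
#' @param recording recording identifier; defaults to the file name.
#' @return An [annotation_set()].
#' @export
read_textgrid <- function(path, tier, individual = "unknown",
                          recording = basename(path)) {
  tiers <- parse_textgrid(path)
  names(tiers) <- vapply(tiers, `[[`, "", "name")
  if (!tier %in% names(tiers)) {
    stop("tier '", tier, "' not found; available tiers: ",
         paste(names(tiers), collapse = ", "))
  }
  tr <- tiers[[tier]]
  if (!identical(tr$class, "IntervalTier")) {
    stop("tier '", tier, "' is a ", tr$class,
         ", not an IntervalTier; point tiers carry no element intervals")
  }
  keep <- !is.na(tr$label) & tr$label != ""
  annotation_set(
    onset = tr$xmin[keep], offset = tr$xmax[keep],
    element_class = tr$label[keep],
    individual = individual, recording = recording,
    provenance = paste0(path, "#", tier)
  )
}

#' Write an annotation set as a (long-format, UTF-8) Praat TextGrid
#'
#' Gaps between elements are emitted as empty-label intervals so the tier
#' tiles the full time range, as Praat requires.
#'
#' @param a an [annotation_set()]; must contain a single recording.
#' @param path output path.
#' @param tier tier name to write.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(a, path, tier = "elements") {
  validate_annotation_set(a)
  if (length(unique(a$recording)) > 1L) {
    stop("write_textgrid expects a single recording; got ",
         length(unique(a$recording)))
  }
  xmax <- if (nrow(a)) max(a$offset) else 1
  fnum <- function(x) sprintf("%.17g", x)
  # build the tiling: silence fillers between labelled intervals
  iv_min <- numeric(0); iv_max <- numeric(0); iv_lab <- character(0)
  cur <- 0
  if (nrow(a)) {
    for (k in seq_len(nrow(a))) {
      if (a$onset[k] > cur + 1e-12) {
        iv_min <- c(iv_min, cur); iv_max <- c(iv_max, a$onset[k])
        iv_lab <- c(iv_lab, "")
      }
      iv_min <- c(iv_min, a$onset[k]); iv_max <- c(iv_max, a$offset[k])
      iv_lab <- c(iv_lab, a$element_class[k])
      cur <- a$offset[k]
    }
  }
  if (cur < xmax - 1e-12 || length(iv_min) == 0L) {
    iv_min <- c(iv_min, cur); iv_max <- c(iv_max, xmax); iv_lab <- c(iv_lab, "")
  }
  q <- function(s) paste0('"', gsub('"', '""', s), '"')
  out <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    paste0("xmin = ", fnum(0)),
    paste0("xmax = ", fnum(xmax)),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    '        class = "IntervalTier"',
    paste0("        name = ", q(tier)),
    paste0("        xmin = ", fnum(0)),
    paste0("        xmax = ", fnum(xmax)),
    paste0("        intervals: size = ", length(iv_min))
  )
  for (k in seq_along(iv_min)) {
    out <- c(out,
             paste0("        intervals [", k, "]:"),
             paste0("            xmin = ", fnum(iv_min[k])),
             paste0("            xmax = ", fnum(iv_max[k])),
             paste0("            text = ", q(iv_lab[k])))
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}
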