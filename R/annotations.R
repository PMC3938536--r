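#' Read vowel annotations from a CSV file or Praat TextGrid
#'
#' Vowel boundaries are taken from manual annotation, not automatic
#' segmentation. Two formats are accepted:
#'
#' * CSV with columns `word, pattern, v1_on_s, v1_off_s, v2_on_s,
#'   v2_off_s` (pattern may be empty for the built-in stimulus words);
#' * Praat TextGrid (long or short form) with an interval tier whose
#'   non-empty labels mark the two vowels of each word as
#'   `"<word>/V1"` and `"<word>/V2"` (separators `/`, `:`, `.` or space
#'   are accepted, e.g. `"potato V1"`). Consecutive V1/V2 labels of the
#'   same word are paired into one token. An optional `"<word>/<SW|WS>/V1"`
#'   form carries an explicit pattern for words not in the built-in lists.
#'
#' @param path Path to the annotation file.
#' @param tier Tier name for TextGrid input (default `"vowels"`).
#' @param format `"auto"` (by extension), `"csv"`, or `"textgrid"`.
#' @return A [word_tokens()] data frame.
#' @export
read_vowel_annotations <- function(path, tier = "vowels",
                                   format = c("auto", "csv", "textgrid")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.textgrid$", path, ignore.case = TRUE))
      "textgrid" else "csv"
  }
  if (format == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("word", "v1_on_s", "v1_off_s", "v2_on_s", "v2_off_s")
    if (!all(need %in% names(d)))
      stop_validation("annotation CSV needs columns ",
                      paste(need, collapse = ", "), ": ", path)
    pat <- if ("pattern" %in% names(d)) d$pattern else NULL
    word_tokens(d$word, d$v1_on_s, d$v1_off_s, d$v2_on_s, d$v2_off_s, pat)
  } else {
    iv <- read_textgrid_tier(path, tier)
    pair_vowel_labels(iv, path)
  }
}

# Parse one interval tier out of a Praat TextGrid (long or short form).
# Returns data.frame(start, end, label) of non-empty-labelled intervals.
read_textgrid_tier <- function(path, tier) {
  if (!file.exists(path))
    stop_validation("TextGrid does not exist: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!any(grepl("ooTextFile", lines[seq_len(min(3, length(lines)))])))
    stop_validation("not a Praat TextGrid (missing ooTextFile header): ",
                    path)
  quoted <- regmatches(lines, regexpr("\"[^\"]*\"", lines))
  # locate tier by its quoted name following an IntervalTier class marker
  class_idx <- grep("\"IntervalTier\"", lines)
  if (!length(class_idx))
    stop_validation("no IntervalTier found in ", path)
  name_line <- NA_integer_
  for (ci in class_idx) {
    # tier name is the next quoted string after the class line
    cand <- ci + which(grepl("\"", lines[(ci + 1):min(ci + 3, length(lines))]))[1]
    if (!is.na(cand) && grepl(paste0("\"", tier, "\""), lines[cand])) {
      name_line <- ci
      break
    }
  }
  if (is.na(name_line))
    stop_validation("tier '", tier, "' not found in ", path)
  # tier block runs until the next IntervalTier marker or EOF
  nxt <- class_idx[class_idx > name_line]
  block <- lines[name_line:(if (length(nxt)) nxt[1] - 1 else length(lines))]
  nums <- suppressWarnings(as.numeric(sub("^.*=\\s*", "",
                                          grep("=", block, value = TRUE))))
  # long form: xmin/xmax/text per interval
  xm <- grep("xmin\\s*=", block); xx <- grep("xmax\\s*=", block)
  tx <- grep("text\\s*=", block)
  get_num <- function(l) as.numeric(sub(".*=\\s*", "", l))
  get_txt <- function(l) sub("^\\s*text\\s*=\\s*\"(.*)\"\\s*$", "\\1", l)
  if (length(tx)) {
    n <- length(tx)
    starts <- get_num(block[xm[(length(xm) - n + 1):length(xm)]])
    ends <- get_num(block[xx[(length(xx) - n + 1):length(xx)]])
    labels <- get_txt(block[tx])
  } else {
    # short form: after name, xmin xmax n, then triples (xmin xmax "text")
    toks <- block[-1]
    toks <- trimws(toks[trimws(toks) != ""])
    if (length(toks) < 3)
      stop_validation("malformed short-form tier '", tier, "' in ", path)
    n <- as.integer(toks[3])
    starts <- ends <- numeric(n); labels <- character(n)
    for (i in seq_len(n)) {
      base <- 3 + (i - 1) * 3
      starts[i] <- as.numeric(toks[base + 1])
      ends[i] <- as.numeric(toks[base + 2])
      labels[i] <- gsub("^\"|\"$", "", toks[base + 3])
    }
  }
  keep <- !is.na(labels) & trimws(labels) != ""
  data.frame(start = starts[keep], end = ends[keep],
             label = trimws(labels[keep]), stringsAsFactors = FALSE)
}

# pair "<word>[/pattern]/V1" + ".../V2" labels into word tokens
pair_vowel_labels <- function(iv, path) {
  m <- regexec("^(.*?)(?:[/: .]+(SW|WS))?[/: .]+[Vv]([12])$", iv$label)
  parts <- regmatches(iv$label, m)
  bad <- which(vapply(parts, length, 1L) == 0L)
  if (length(bad))
    stop_validation("unparseable vowel label(s) in ", path, ": ",
                    paste(iv$label[bad], collapse = ", "))
  word <- vapply(parts, `[`, "", 2)
  patt <- vapply(parts, `[`, "", 3)
  vno <- vapply(parts, `[`, "", 4)
  ord <- order(iv$start)
  iv <- iv[ord, ]
  word <- word[ord]; patt <- patt[ord]; vno <- vno[ord]
  i1 <- which(vno == "1")
  tok <- lapply(i1, function(i) {
    j <- i + 1
    if (j > nrow(iv) || vno[j] != "2" || word[j] != word[i])
      stop_validation("V1 label '", iv$label[i], "' in ", path,
                      " is not followed by a matching V2")
    data.frame(word = word[i],
               pattern = if (nzchar(patt[i])) patt[i] else NA_character_,
               v1_on = iv$start[i], v1_off = iv$end[i],
               v2_on = iv$start[j], v2_off = iv$end[j])
  })
  d <- do.call(rbind, tok)
  word_tokens(d$word, d$v1_on, d$v1_off, d$v2_on, d$v2_off, d$pattern)
}

#' Write word tokens as a long-form Praat TextGrid
#'
#' Writes one interval tier with labels `"<word>/V1"` and `"<word>/V2"`
#' (pattern included as `"<word>/<pattern>/V1"` for words outside the
#' built-in stimulus lists), readable by [read_vowel_annotations()] and by
#' Praat.
#'
#' @param tokens A [word_tokens()] data frame.
#' @param path Output path.
#' @param tier Tier name (default `"vowels"`).
#' @param xmax Total duration of the annotated recording in seconds
#'   (default: last vowel offset).
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(tokens, path, tier = "vowels",
                           xmax = max(tokens$v2_off)) {
  tokens <- as.data.frame(tokens)
  lab <- function(i, v) {
    w <- tokens$word[i]
    if (is.na(stress_pattern(w)))
      paste0(w, "/", tokens$pattern[i], "/V", v)
    else paste0(w, "/V", v)
  }
  # build full tiling including empty gaps
  b <- c(0)
  segs <- list()
  cur <- 0
  tokens <- tokens[order(tokens$v1_on), ]
  for (i in seq_len(nrow(tokens))) {
    t <- tokens[i, ]
    if (t$v1_on > cur) segs[[length(segs) + 1]] <- c(cur, t$v1_on, "")
    segs[[length(segs) + 1]] <- c(t$v1_on, t$v1_off, lab(i, 1))
    if (t$v2_on > t$v1_off) segs[[length(segs) + 1]] <- c(t$v1_off, t$v2_on, "")
    segs[[length(segs) + 1]] <- c(t$v2_on, t$v2_off, lab(i, 2))
    cur <- t$v2_off
  }
  if (xmax > cur) segs[[length(segs) + 1]] <- c(cur, xmax, "")
  n <- length(segs)
  out <- c(
    "File type = \"ooTextFile\"",
    "Object class = \"TextGrid\"",
    "",
    "xmin = 0",
    sprintf("xmax = %.10g", xmax),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    "        class = \"IntervalTier\"",
    sprintf("        name = \"%s\"", tier),
    "        xmin = 0",
    sprintf("        xmax = %.10g", xmax),
    sprintf("        intervals: size = %d", n))
  for (i in seq_len(n)) {
    s <- segs[[i]]
    out <- c(out,
             sprintf("        intervals [%d]:", i),
             sprintf("            xmin = %.10g", as.numeric(s[1])),
             sprintf("            xmax = %.10g", as.numeric(s[2])),
             sprintf("            text = \"%s\"", s[3]))
  }
  writeLines(out, path)
  invisible(path)
}
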