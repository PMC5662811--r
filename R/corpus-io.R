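# Readers/writers for prescription corpora, herb attribute tables and
# label vocabularies.
#
# Canonical on-disk layout:
#   corpus.jsonl  one prescription per line:
#     {"id":"p1","herbs":[["Ephedrae Herba",9],["Glycyrrhizae Radix",3]],
#      "labels":["relieving exterior syndrome"]}
#   corpus.tsv    columns id / herbs / labels with
#     herbs  = "Ephedrae Herba=9;Glycyrrhizae Radix=3"
#     labels = "relieving exterior syndrome" (";"-separated)
#   attrs.tsv     columns name, dose_min, dose_max, nature_flavor,
#     channel_tropism, efficiency (";"-separated terms; a "slightly "
#     prefix encodes attribute weight 0.5)
#   labels.txt    one label per line (fixes the label vocabulary and its
#     order; otherwise the vocabulary is the sorted union of observed
#     labels)

.emptyHerbTable <- function(names = character()) {
  data.frame(name = names,
             doseMin = rep(NA_real_, length(names)),
             doseMax = rep(NA_real_, length(names)),
             natureFlavor = rep("", length(names)),
             channelTropism = rep("", length(names)),
             efficiency = rep("", length(names)),
             stringsAsFactors = FALSE)
}

#' Construct a HerbCorpus from in-memory records
#'
#' Assigns stable integer herb ids in first-seen order across the
#' prescription list, attaches herb metadata by name, and fixes the label
#' vocabulary (the sorted union of observed labels unless `labelNames` is
#' supplied).
#'
#' @param records list; each element a list with `id` (character),
#'   `herbs` (character vector of herb names), `doses` (numeric grams) and
#'   `labels` (character vector, possibly empty).
#' @param herbTable optional data.frame in the attribute-table layout of
#'   [readAttributeTable()]; herbs seen in prescriptions but absent from
#'   the table get an NA dosage range and empty attributes.
#' @param labelNames optional character vector fixing the label vocabulary
#'   and its order; labels observed in records but absent from it are an
#'   error.
#' @return a validated [HerbCorpus-class]
#' @export
makeCorpus <- function(records, herbTable = NULL, labelNames = NULL) {
  if (length(records) == 0)
    stop("corpus must contain at least one prescription")
  seen <- character()
  for (r in records) seen <- c(seen, r$herbs[!(r$herbs %in% seen)])
  if (is.null(herbTable)) {
    herbs <- .emptyHerbTable(seen)
  } else {
    extra <- setdiff(seen, herbTable$name)
    herbs <- rbind(herbTable[, names(.emptyHerbTable())],
                   .emptyHerbTable(extra))
    # keep first-seen order for herbs in prescriptions; table-only herbs
    # (attribute rows never used) follow after
    ord <- c(match(seen, herbs$name),
             which(!(herbs$name %in% seen)))
    herbs <- herbs[ord, , drop = FALSE]
  }
  rownames(herbs) <- NULL
  obs <- sort(unique(unlist(lapply(records, `[[`, "labels"))))
  if (is.null(labelNames)) {
    labelNames <- obs
  } else if (length(bad <- setdiff(obs, labelNames))) {
    stop("labels not in supplied vocabulary: ", paste(bad, collapse = ", "))
  }
  pres <- lapply(records, function(r) {
    hid <- match(r$herbs, herbs$name)
    if (anyNA(hid))
      stop("parse error in record '", r$id, "': unresolvable herb name")
    list(id = as.character(r$id),
         herbIds = as.integer(hid),
         doses = as.numeric(r$doses),
         labels = as.integer(match(r$labels, labelNames)))
  })
  new("HerbCorpus", prescriptions = pres, herbs = herbs,
      labelNames = as.character(labelNames))
}

#' Read a prescription corpus
#'
#' @param path path to a JSON-lines or TSV corpus file (see the package
#'   README for the schemas).
#' @param format `"jsonl"` or `"tsv"`.
#' @param attrPath optional path to a herb-attribute TSV
#'   ([readAttributeTable()]).
#' @param labelPath optional path to a plain-text label vocabulary file,
#'   one label per line; fixes K and the label order.
#' @return a [HerbCorpus-class]
#' @export
readCorpus <- function(path, format = c("jsonl", "tsv"),
                       attrPath = NULL, labelPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("corpus file not found: ", path)
  records <- if (format == "jsonl") .readJsonl(path) else .readTsv(path)
  herbTable <- if (!is.null(attrPath)) readAttributeTable(attrPath)
  labs <- if (!is.null(labelPath)) {
    x <- readLines(labelPath, warn = FALSE)
    x[nzchar(x)]
  }
  makeCorpus(records, herbTable = herbTable, labelNames = labs)
}

.readJsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop("parse error on line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    if (is.null(rec$id) || is.null(rec$herbs))
      stop("parse error in record on line ", i, ": missing id or herbs")
    herbs <- vapply(rec$herbs, function(h) as.character(h[[1]]), "")
    doses <- vapply(rec$herbs, function(h) as.numeric(h[[2]]), 0)
    if (any(!is.finite(doses)) || any(doses <= 0))
      stop("parse error in record '", rec$id, "': non-positive dosage")
    list(id = rec$id, herbs = herbs, doses = doses,
         labels = as.character(unlist(rec$labels)))
  })
}

.readTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("id", "herbs", "labels") %in% names(df)))
    stop("corpus TSV must have columns id, herbs, labels")
  lapply(seq_len(nrow(df)), function(i) {
    entries <- strsplit(df$herbs[i], ";", fixed = TRUE)[[1]]
    kv <- strsplit(entries, "=", fixed = TRUE)
    if (any(lengths(kv) != 2))
      stop("parse error in record '", df$id[i], "': bad herb entry")
    doses <- as.numeric(vapply(kv, `[[`, "", 2L))
    if (any(!is.finite(doses)) || any(doses <= 0))
      stop("parse error in record '", df$id[i], "': non-positive dosage")
    labs <- strsplit(df$labels[i], ";", fixed = TRUE)[[1]]
    list(id = df$id[i],
         herbs = vapply(kv, `[[`, "", 1L),
         doses = doses,
         labels = labs[nzchar(labs)])
  })
}

#' Write a prescription corpus
#'
#' Lossless inverse of [readCorpus()]: `readCorpus(writeCorpus(x))`
#' reproduces the corpus field-for-field (use [writeAttributeTable()]
#' alongside to persist herb metadata).
#'
#' @param corpus a [HerbCorpus-class]
#' @param path output file path
#' @param format `"jsonl"` or `"tsv"`
#' @return `path`, invisibly
#' @export
writeCorpus <- function(corpus, path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  validObject(corpus)
  nm <- herbNames(corpus)
  ln <- corpus@labelNames
  lines <- vapply(corpus@prescriptions, function(p) {
    if (format == "jsonl") {
      herbs <- mapply(function(h, d) list(h, d),
                      nm[p$herbIds], p$doses, SIMPLIFY = FALSE,
                      USE.NAMES = FALSE)
      jsonlite::toJSON(list(id = p$id, herbs = herbs,
                            labels = as.list(ln[p$labels])),
                       auto_unbox = TRUE, digits = NA)
    } else {
      paste(p$id,
            paste(nm[p$herbIds], p$doses, sep = "=", collapse = ";"),
            paste(ln[p$labels], collapse = ";"),
            sep = "\t")
    }
  }, "")
  if (format == "tsv") lines <- c("id\therbs\tlabels", lines)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a herb attribute table
#'
#' The TSV carries one row per herb: `name`, `dose_min`, `dose_max`
#' (usual dosage range in grams; blank when unknown) and the three
#' attribute groups `nature_flavor`, `channel_tropism`, `efficiency` as
#' `;`-separated term lists. A `"slightly "` prefix on a term encodes
#' attribute weight 0.5; plain terms weigh 1.0.
#'
#' @param path TSV file path
#' @return data.frame with columns `name`, `doseMin`, `doseMax`,
#'   `natureFlavor`, `channelTropism`, `efficiency`
#' @export
readAttributeTable <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("name", "dose_min", "dose_max", "nature_flavor",
            "channel_tropism", "efficiency")
  if (!all(need %in% names(df)))
    stop("attribute table must have columns: ", paste(need, collapse = ", "))
  out <- data.frame(name = df$name,
                    doseMin = suppressWarnings(as.numeric(df$dose_min)),
                    doseMax = suppressWarnings(as.numeric(df$dose_max)),
                    natureFlavor = df$nature_flavor,
                    channelTropism = df$channel_tropism,
                    efficiency = df$efficiency,
                    stringsAsFactors = FALSE)
  bad <- !is.na(out$doseMin) & !is.na(out$doseMax) &
    out$doseMin > out$doseMax
  if (any(bad))
    stop("dose_min > dose_max for herb(s): ",
         paste(out$name[bad], collapse = ", "))
  out
}

#' @rdname readAttributeTable
#' @param corpus a [HerbCorpus-class] whose herb table is written
#' @return `writeAttributeTable` returns `path` invisibly
#' @export
writeAttributeTable <- function(corpus, path) {
  h <- herbTable(corpus)
  out <- data.frame(name = h$name,
                    dose_min = ifelse(is.na(h$doseMin), "", h$doseMin),
                    dose_max = ifelse(is.na(h$doseMax), "", h$doseMax),
                    nature_flavor = h$natureFlavor,
                    channel_tropism = h$channelTropism,
                    efficiency = h$efficiency,
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a `;`-separated attribute term string
#'
#' @param x character scalar, e.g. `"spicy;slightly bitter;warm"`
#' @return named numeric vector of weights (1.0, or 0.5 for terms carrying
#'   the `"slightly "` prefix), named by the bare term
#' @export
parseAttributeTerms <- function(x) {
  if (is.na(x) || !nzchar(x)) return(setNames(numeric(0), character(0)))
  terms <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
  terms <- terms[nzchar(terms)]
  slight <- startsWith(terms, "slightly ")
  bare <- ifelse(slight, sub("^slightly ", "", terms), terms)
  setNames(ifelse(slight, 0.5, 1.0), bare)
}

#' Validate herb metadata completeness
#'
#' Returns (not signals) one warning string per herb lacking a usual
#' dosage range or lacking all attribute terms. Such herbs still work:
#' dose standardization falls back to a standard weight of 1 and the
#' attribute vector contribution is all-zero. A range with
#' `doseMin > doseMax` is an invariant breach and errors at construction,
#' not here.
#'
#' @param corpus a [HerbCorpus-class]
#' @return character vector of warnings (empty when the table is complete)
#' @export
validateAttributeTable <- function(corpus) {
  h <- herbTable(corpus)
  warnings <- character()
  noRange <- is.na(h$doseMin) | is.na(h$doseMax)
  noAttr <- !nzchar(h$natureFlavor) & !nzchar(h$channelTropism) &
    !nzchar(h$efficiency)
  for (i in which(noRange))
    warnings <- c(warnings, paste0(
      "herb '", h$name[i], "' has no usual dosage range; ",
      "standardized dose falls back to 1"))
  for (i in which(noAttr))
    warnings <- c(warnings, paste0(
      "herb '", h$name[i], "' has no attribute terms"))
  warnings
}

#' Binary label matrix of a corpus
#'
#' @param corpus a [HerbCorpus-class]
#' @return N x K 0/1 matrix; entry (p, k) is 1 iff prescription p carries
#'   label k. Column names are the label vocabulary.
#' @export
labelMatrix <- function(corpus) {
  K <- nLabels(corpus)
  N <- nPrescriptions(corpus)
  Y <- matrix(0L, N, K, dimnames = list(
    vapply(corpus@prescriptions, `[[`, "", "id"), corpus@labelNames))
  for (i in seq_len(N)) Y[i, corpus@prescriptions[[i]]$labels] <- 1L
  Y
}
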