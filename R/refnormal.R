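# Invariable-locus selection and reference-normal construction.

#' Modal length of a length multiset
#'
#' @param lengths A length multiset: numeric vector of lengths, named
#'   count vector, or data.frame with \code{length} and \code{count}.
#' @return A list with \code{length} (the most frequent length; ties broken
#'   toward the smallest length) and \code{count} (its read count).
#' @examples
#' modalLength(c(`10` = 2, `11` = 1))  # length 10, count 2
#' modalLength(c(`10` = 2, `12` = 2))  # tie -> smallest length
#' @export
modalLength <- function(lengths) {
  lc <- .asLengthCounts(lengths)
  i <- which.max(lc$count)  # lengths sorted ascending: first max = smallest
  list(length = lc$len[i], count = lc$count[i])
}

# Long table of per-sample, per-locus modal lengths across a normal cohort.
# Only (sample, locus) pairs with depth >= minReads are kept ("informative").
.cohortModalTable <- function(normals, minReads) {
  stopifnot(length(normals) >= 1L,
            all(vapply(normals, methods::is, logical(1), "LengthProfile")))
  dt <- data.table::rbindlist(lapply(normals, function(p)
    data.table::data.table(sample_id = p@sampleId, p@counts)))
  if (!nrow(dt)) stop("normal cohort has no profiled loci", call. = FALSE)
  # modal length per (sample, locus): max count, smallest length on ties
  data.table::setorder(dt, sample_id, locus_id, -count, length)
  modal <- dt[, .(depth = sum(count), modal_length = length[1L],
                  modal_count = count[1L]), by = .(sample_id, locus_id)]
  modal[depth >= minReads]
}

# Consensus modal length per locus: most common per-sample modal length,
# smallest on ties; agreement = fraction of informative samples sharing it.
.lociConsensus <- function(modal) {
  cons <- modal[, {
    tab <- sort(table(modal_length), decreasing = TRUE)
    best <- as.integer(names(tab)[tab == tab[1L]])
    cl <- min(best)
    .(n_informative = .N,
      consensus_length = cl,
      agreement = sum(modal_length == cl) / .N)
  }, by = locus_id]
  data.table::setorder(cons, locus_id)
  cons
}

#' Select invariable microsatellite loci from a normal cohort
#'
#' A locus is \emph{invariable} when strictly more than
#' \code{agreementThreshold} (default 95\%) of the informative normal
#' samples (depth \eqn{\ge} \code{minReads}) share the same modal tract
#' length, and at least \code{minNormals} normals are informative there.
#'
#' @param normals List of \code{\linkS4class{LengthProfile}} objects for
#'   the normal cohort.
#' @param cfg A \code{\link{detectionConfig}}.
#' @return A list with \code{invariable} (character vector of locus ids)
#'   and \code{summary} (data.frame: \code{locus_id},
#'   \code{n_informative}, \code{consensus_length}, \code{agreement},
#'   \code{invariable}).
#' @seealso \code{\link{buildReferenceNormal}}
#' @export
selectInvariable <- function(normals, cfg = detectionConfig()) {
  if (length(normals) < cfg$minNormals)
    stop("normal cohort has ", length(normals), " samples but ",
         "detectionConfig(minNormals=", cfg$minNormals, ") requires more; ",
         "override minNormals for small cohorts", call. = FALSE)
  modal <- .cohortModalTable(normals, cfg$minReads)
  if (!nrow(modal))
    stop("no locus reaches ", cfg$minReads, " reads in any normal sample",
         call. = FALSE)
  cons <- .lociConsensus(modal)
  cons[, invariable := n_informative >= cfg$minNormals &
         agreement > cfg$agreementThreshold]
  list(invariable = cons$locus_id[cons$invariable],
       summary = as.data.frame(cons))
}

#' Build the synthetic reference normal
#'
#' For every invariable locus, the reference normal repeats the cohort
#' consensus modal length \code{ref_count} times, where \code{ref_count}
#' is the median -- across informative normals -- of each sample's read
#' count at its own modal length, rounded half-up and floored at
#' \code{minReads}.
#'
#' @param normals List of \code{\linkS4class{LengthProfile}} objects.
#' @param invariable Character vector of invariable locus ids (from
#'   \code{\link{selectInvariable}}).
#' @param cfg A \code{\link{detectionConfig}}.
#' @return A \code{\linkS4class{ReferenceNormal}}.
#' @export
buildReferenceNormal <- function(normals, invariable,
                                 cfg = detectionConfig()) {
  stopifnot(is.character(invariable))
  modal <- .cohortModalTable(normals, cfg$minReads)
  modal <- modal[locus_id %in% invariable]
  miss <- setdiff(invariable, unique(modal$locus_id))
  if (length(miss))
    stop("invariable locus absent from every normal profile: ",
         paste(head(miss, 5), collapse = ", "), call. = FALSE)
  cons <- .lociConsensus(modal)
  med <- modal[, .(ref_count = pmax(cfg$minReads,
                                    roundHalfUp(median(modal_count)))),
               by = locus_id]
  tb <- merge(cons[, .(locus_id, ref_length = consensus_length)], med,
              by = "locus_id")
  data.table::setorder(tb, locus_id)
  methods::new("ReferenceNormal", table = as.data.frame(tb))
}

#' Intersect invariable-locus sets across cancer cohorts
#'
#' Cross-cancer model building restricts to loci invariable in every
#' cohort; this is the plain set intersection.
#'
#' @param ... Character vectors of invariable locus ids (or a single list
#'   of them).
#' @return Character vector of locus ids invariable in all cohorts.
#' @export
intersectInvariable <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]])) sets <- sets[[1]]
  stopifnot(length(sets) >= 1L)
  Reduce(intersect, sets)
}

#' Write / read a reference normal
#'
#' Tab-separated \code{locus_id ref_length ref_count} with a versioned
#' header comment.
#'
#' @param ref A \code{\linkS4class{ReferenceNormal}}.
#' @param path File path.
#' @return \code{writeReferenceNormal}: \code{path} invisibly;
#'   \code{readReferenceNormal}: a \code{ReferenceNormal}.
#' @export
writeReferenceNormal <- function(ref, path) {
  stopifnot(methods::is(ref, "ReferenceNormal"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#format=msirna_refnormal_v1", con)
  utils::write.table(ref@table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeReferenceNormal
#' @export
readReferenceNormal <- function(path) {
  first <- readLines(path, n = 1L)
  if (!identical(first, "#format=msirna_refnormal_v1"))
    stop("not an msirna reference-normal file: ", path, call. = FALSE)
  tb <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#",
                          colClasses = c("character", "integer", "integer"))
  methods::new("ReferenceNormal", table = tb)
}
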