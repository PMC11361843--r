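# Unstable-locus calling: discrete two-sample KS test, FDR control, and
# group comparison of per-sample unstable counts.

# Upper tail of the asymptotic Kolmogorov distribution,
# Q(lambda) = 2 * sum_{k>=1} (-1)^(k-1) exp(-2 k^2 lambda^2).
.kolmogorovQ <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- seq_len(101)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov test on discrete length multisets
#'
#' Computes \eqn{D = \sup_t |F_x(t) - F_y(t)|} with both empirical CDFs
#' evaluated on the merged support (ties are intrinsic to discrete tract
#' lengths and are handled exactly in D).  The default p-value comes from
#' the asymptotic Kolmogorov distribution at
#' \eqn{\sqrt{n_x n_y / (n_x + n_y)}\, D}, which is conservative under
#' heavy ties; with \code{method = "exact"} (or a
#' \code{\link{detectionConfig}} requesting \code{ks_exact_smalln} and both
#' sizes at most \code{exactNCap}) the exact conditional distribution of D
#' given the tie pattern is used (\code{\link[stats]{psmirnov}}).
#'
#' @param x,y Length multisets: numeric vectors of lengths, named count
#'   vectors, or data.frames with \code{length}/\code{count} columns.
#' @param method \code{"asymptotic"} (default) or \code{"exact"}.
#' @return A list with \code{D}, \code{p}, \code{n_x}, \code{n_y}.
#' @examples
#' ksTwoSample(c(`10` = 5), c(`12` = 5))      # disjoint: D = 1
#' ksTwoSample(rep(10, 5), rep(10, 5))        # identical: D = 0, p = 1
#' @export
ksTwoSample <- function(x, y, method = c("asymptotic", "exact")) {
  method <- match.arg(method)
  lx <- .asLengthCounts(x)
  ly <- .asLengthCounts(y)
  nx <- sum(lx$count); ny <- sum(ly$count)
  support <- sort(unique(c(lx$len, ly$len)))
  cx <- numeric(length(support)); cx[match(lx$len, support)] <- lx$count
  cy <- numeric(length(support)); cy[match(ly$len, support)] <- ly$count
  D <- max(abs(cumsum(cx) / nx - cumsum(cy) / ny))
  if (method == "exact") {
    z <- c(rep(lx$len, lx$count), rep(ly$len, ly$count))
    p <- 1 - stats::psmirnov(D - 1e-12, sizes = c(nx, ny), z = z,
                             two.sided = TRUE, exact = TRUE)
    p <- min(1, max(p, .Machine$double.xmin))
  } else {
    neff <- nx * ny / (nx + ny)
    p <- .kolmogorovQ(sqrt(neff) * D)
    p <- max(p, .Machine$double.xmin)
  }
  list(D = D, p = p, n_x = as.integer(nx), n_y = as.integer(ny))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment in the input order; rejecting at
#' \code{q < alpha} reproduces the classical BH step-up rule.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param method \code{"BH"} (default) or \code{"BY"}.
#' @return q-values in the input order.
#' @examples
#' bhFdr(c(0.005, 0.5))  # 0.01, 0.5
#' @export
bhFdr <- function(p, method = c("BH", "BY")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = method)
}

# Length multiset of a locus in either a LengthProfile or a
# ReferenceNormal (the latter is the degenerate multiset ref_length
# repeated ref_count times, exactly as the reference normal is defined).
.locusMultiset <- function(x, id) {
  if (methods::is(x, "ReferenceNormal")) {
    row <- x@table[x@table$locus_id == id, ]
    if (!nrow(row)) return(NULL)
    return(data.frame(length = row$ref_length, count = row$ref_count))
  }
  sub <- x@counts[x@counts$locus_id == id, c("length", "count")]
  if (!nrow(sub)) NULL else sub
}

#' Call unstable microsatellite loci for one tumor sample
#'
#' Every locus of the analysis set with at least \code{minReads} reads in
#' the tumor \emph{and} in the normal source is tested with the
#' two-sample KS test (\code{\link{ksTwoSample}}); p-values are adjusted
#' by Benjamini-Hochberg across all tested loci of the sample, and a locus
#' is \emph{unstable} when its q-value falls below \code{fdrAlpha}.
#' A \code{\linkS4class{ReferenceNormal}} contributes its modal length
#' repeated \code{ref_count} times.  The per-sample summary stratifies
#' tested/unstable counts by genic region and repeat class (with
#' \code{ALL} marginals).
#'
#' @param tumor The tumor \code{\linkS4class{LengthProfile}}.
#' @param normal A matched-normal \code{\linkS4class{LengthProfile}} or a
#'   \code{\linkS4class{ReferenceNormal}}.
#' @param catalog The \code{\linkS4class{MsCatalog}} providing region and
#'   repeat-class strata.
#' @param cfg A \code{\link{detectionConfig}}.
#' @param loci Optional restriction of the analysis set to these locus ids
#'   (typically the invariable set; defaults to all loci shared by catalog
#'   and normal source).
#' @return An \code{\linkS4class{InstabilityResult}}.
#' @export
callUnstable <- function(tumor, normal, catalog, cfg = detectionConfig(),
                         loci = NULL) {
  stopifnot(methods::is(tumor, "LengthProfile"),
            methods::is(catalog, "MsCatalog"))
  set <- locusIds(catalog)
  normIds <- if (methods::is(normal, "ReferenceNormal")) locusIds(normal)
             else locusIds(normal)
  set <- intersect(set, normIds)
  if (!is.null(loci)) set <- intersect(set, loci)
  if (!length(set))
    stop("empty analysis locus set (catalog, normal source and 'loci' do ",
         "not intersect)", call. = FALSE)

  tdep <- locusDepths(tumor)
  ndep <- locusDepths(normal)
  testable <- set[!is.na(tdep[set]) & tdep[set] >= cfg$minReads &
                    !is.na(ndep[set]) & ndep[set] >= cfg$minReads]
  if (!length(testable))
    stop("no locus reaches ", cfg$minReads, " reads on both sides: ",
         "coverage too low or analysis locus set too small", call. = FALSE)

  useExact <- cfg$test == "ks_exact_smalln"
  res <- lapply(testable, function(id) {
    xs <- .locusMultiset(tumor, id)
    ys <- .locusMultiset(normal, id)
    meth <- if (useExact && sum(xs$count) <= cfg$exactNCap &&
                  sum(ys$count) <= cfg$exactNCap) "exact" else "asymptotic"
    ksTwoSample(xs, ys, method = meth)
  })
  mc <- S4Vectors::mcols(catalog)
  idx <- match(testable, mc$locus_id)
  calls <- data.frame(
    locus_id = testable,
    region = mc$region[idx],
    class = classifyMotif(mc$motif[idx]),
    n_tumor = vapply(res, `[[`, integer(1), "n_x"),
    n_normal = vapply(res, `[[`, integer(1), "n_y"),
    D = vapply(res, `[[`, numeric(1), "D"),
    p = vapply(res, `[[`, numeric(1), "p"))
  calls$q <- bhFdr(calls$p, method = cfg$fdrMethod)
  calls$unstable <- calls$q < cfg$fdrAlpha

  methods::new("InstabilityResult", sampleId = tumor@sampleId,
               calls = calls,
               summary = .summarizeCalls(calls),
               config = unclass(cfg))
}

# region x class summary with ALL marginals
.summarizeCalls <- function(calls) {
  regs <- c("CDS", "UTR5", "UTR3", "OTHER", "ALL")
  clss <- c("mono", "di", "tri", "tetra", "ALL")
  grid <- expand.grid(region = regs, class = clss,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n_tested <- mapply(function(r, k) {
    sel <- (r == "ALL" | calls$region == r) & (k == "ALL" | calls$class == k)
    sum(sel)
  }, grid$region, grid$class)
  grid$n_unstable <- mapply(function(r, k) {
    sel <- (r == "ALL" | calls$region == r) & (k == "ALL" | calls$class == k)
    sum(calls$unstable[sel])
  }, grid$region, grid$class)
  grid
}

#' Compare unstable-locus counts between two sample groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test: exact for small
#' samples without ties, normal approximation with tie correction
#' otherwise.
#'
#' @param countsA,countsB Numeric vectors of per-sample unstable-locus
#'   counts for the two groups (e.g. MSI-H vs MSS).
#' @return A list with \code{W} (rank-sum statistic of the first group)
#'   and \code{p}.
#' @examples
#' compareGroups(c(1, 2, 3), c(4, 5, 6))$p  # exact: 0.1
#' @export
compareGroups <- function(countsA, countsB) {
  if (!length(countsA) || !length(countsB))
    stop("both groups must be non-empty", call. = FALSE)
  wt <- suppressWarnings(stats::wilcox.test(countsA, countsB,
                                            alternative = "two.sided"))
  list(W = unname(wt$statistic), p = wt$p.value)
}

#' Write instability calls and summary
#'
#' @param result An \code{\linkS4class{InstabilityResult}}.
#' @param callsPath,summaryPath Output TSV paths (either may be
#'   \code{NULL} to skip).
#' @return \code{result}, invisibly.
#' @export
writeInstabilityResult <- function(result, callsPath = NULL,
                                   summaryPath = NULL) {
  stopifnot(methods::is(result, "InstabilityResult"))
  if (!is.null(callsPath))
    utils::write.table(result@calls, callsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(summaryPath))
    utils::write.table(cbind(sample_id = result@sampleId, result@summary),
                       summaryPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(result)
}
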