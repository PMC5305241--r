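# Single-marker GLM association: ordinary least squares of a trait on
# [intercept | structure covariates | marker factor], with a partial F test
# of the marker against the covariates-only model.

#' Encode genotype calls as design columns
#'
#' The marker is a categorical factor (k-1 treatment indicators); missing and
#' "unresolved" calls become NA. A monomorphic marker is flagged, not an
#' error, so a scan can skip it and continue.
#'
#' @param calls Character or factor vector of genotype calls.
#' @return A list: \code{ok} (logical), \code{reason} (why skipped, or NA),
#'   \code{factor} (the cleaned factor), \code{columns} (n x (k-1) indicator
#'   matrix, complete rows only defined by \code{!is.na(factor)}).
#' @export
encodeMarker <- function(calls) {
  f <- as.character(calls)
  f[f %in% c("", "NA", "unresolved")] <- NA_character_
  f <- factor(f)
  k <- nlevels(f)
  if (k < 2L) {
    return(list(ok = FALSE, reason = "monomorphic", factor = f,
                columns = NULL))
  }
  mm <- stats::model.matrix(~g, data = data.frame(g = f[!is.na(f)]))
  list(ok = TRUE, reason = NA_character_, factor = f,
       columns = mm[, -1L, drop = FALSE])
}

#' Fit one marker-trait association
#'
#' OLS of the trait on intercept + covariates + marker factor; the marker is
#' tested with a partial F against the covariates-only model, and its
#' incremental variance share is \code{R2 = (RSS_reduced - RSS_full) / TSS}.
#' Rank-deficient designs drop aliased columns with a warning (a marker fully
#' contained in the covariates yields R2 = 0, p = NA).
#'
#' @param y Numeric trait values.
#' @param marker Genotype calls (character/factor), same length as \code{y}.
#' @param covariates Optional numeric matrix/data.frame of structure
#'   covariates (e.g. Q-matrix columns), same rows as \code{y}.
#' @param trait,markerName Labels carried into the output row.
#' @return One-row data.frame: \code{trait}, \code{marker}, \code{n},
#'   \code{df_marker}, \code{F}, \code{p}, \code{r2_marker}, \code{skipped}.
#'   Marker-class effect estimates are attached as attribute
#'   \code{"effects"}.
#' @export
fitSingleMarker <- function(y, marker, covariates = NULL, trait = "trait",
                            markerName = "marker") {
  skipRow <- function(reason, n = NA_integer_) {
    data.frame(trait = trait, marker = markerName, n = n,
               df_marker = NA_integer_, F = NA_real_, p = NA_real_,
               r2_marker = NA_real_, skipped = reason)
  }
  y <- as.numeric(y)
  enc <- encodeMarker(marker)
  cov <- NULL
  if (!is.null(covariates)) {
    cov <- as.matrix(covariates)
    storage.mode(cov) <- "numeric"
    if (is.null(colnames(cov))) {
      colnames(cov) <- paste0("Q", seq_len(ncol(cov)))
    }
  }
  complete <- !is.na(y) & !is.na(enc$factor)
  if (!is.null(cov)) complete <- complete & stats::complete.cases(cov)
  n <- sum(complete)
  f <- droplevels(enc$factor[complete])
  if (nlevels(f) < 2L) return(skipRow("monomorphic", n))
  yv <- y[complete]
  if (stats::sd(yv) == 0) stop("trait has zero variance", call. = FALSE)

  X0 <- cbind(`(Intercept)` = rep(1, n),
              if (!is.null(cov)) cov[complete, , drop = FALSE])
  Xm <- stats::model.matrix(~g, data = data.frame(g = f))[, -1L, drop = FALSE]
  X1 <- cbind(X0, Xm)
  if (n <= ncol(X1) + 2L) {
    stop(sprintf("too few complete cases (n = %d) for %d model columns",
                 n, ncol(X1)), call. = FALSE)
  }
  q0 <- qr(X0); q1 <- qr(X1)
  if (q1$rank < ncol(X1)) {
    warning(sprintf("rank-deficient design for %s/%s: %d aliased column(s) dropped",
                    trait, markerName, ncol(X1) - q1$rank))
  }
  rss <- function(q) sum(qr.resid(q, yv)^2)
  rss0 <- rss(q0); rss1 <- rss(q1)
  tss <- sum((yv - mean(yv))^2)
  dfm <- q1$rank - q0$rank
  dfe <- n - q1$rank
  r2 <- max(0, (rss0 - rss1) / tss)
  if (dfm == 0L) {
    Fst <- NA_real_; p <- NA_real_
  } else {
    Fst <- ((rss0 - rss1) / dfm) / (rss1 / dfe)
    p <- stats::pf(Fst, dfm, dfe, lower.tail = FALSE)
  }
  out <- data.frame(trait = trait, marker = markerName, n = n,
                    df_marker = as.integer(dfm), F = Fst, p = p,
                    r2_marker = r2, skipped = NA_character_)
  coefs <- qr.coef(q1, yv)
  attr(out, "effects") <- coefs[colnames(Xm)]
  out
}

#' Scan all trait x marker pairs
#'
#' One [fitSingleMarker()] record per combination, flagged at both
#' significance thresholds, sorted by p within trait. No multiple-testing
#' correction is applied (the assay's convention is raw thresholds); instead
#' the expected false-positive count under the global null is attached as
#' attribute \code{"expected_false_positives"}.
#'
#' @param traits data.frame of numeric traits with a \code{sample_id} column
#'   (or sample ids as rownames).
#' @param markers data.frame of genotype calls, same id convention.
#' @param covariates Optional numeric covariates, same id convention; rows
#'   are matched by id.
#' @param thresholds Significance thresholds (default 0.01 and 0.001).
#' @return data.frame of association records with logical \code{sig_*}
#'   columns.
#' @export
scanMarkers <- function(traits, markers, covariates = NULL,
                        thresholds = c(0.01, 0.001)) {
  getIds <- function(df) {
    if ("sample_id" %in% names(df)) as.character(df$sample_id)
    else rownames(df)
  }
  dropId <- function(df) df[, setdiff(names(df), "sample_id"), drop = FALSE]
  idT <- getIds(traits); idM <- getIds(markers)
  if (is.null(idT) || is.null(idM)) {
    stop("'traits' and 'markers' need sample ids (column or rownames)",
         call. = FALSE)
  }
  shared <- intersect(idT, idM)
  if (!is.null(covariates)) {
    idC <- getIds(as.data.frame(covariates))
    if (!is.null(idC)) shared <- intersect(shared, idC)
  }
  if (!length(shared)) stop("no overlapping samples", call. = FALSE)
  tDf <- dropId(as.data.frame(traits))[match(shared, idT), , drop = FALSE]
  mDf <- dropId(as.data.frame(markers))[match(shared, idM), , drop = FALSE]
  cMat <- NULL
  if (!is.null(covariates)) {
    cDf <- as.data.frame(covariates)
    idC <- getIds(cDf)
    cMat <- as.matrix(dropId(cDf)[match(shared, idC), , drop = FALSE])
  }
  rows <- list()
  for (tr in names(tDf)) {
    for (mk in names(mDf)) {
      rec <- tryCatch(
        fitSingleMarker(tDf[[tr]], mDf[[mk]], covariates = cMat,
                        trait = tr, markerName = mk),
        error = function(e) {
          data.frame(trait = tr, marker = mk, n = NA_integer_,
                     df_marker = NA_integer_, F = NA_real_, p = NA_real_,
                     r2_marker = NA_real_, skipped = conditionMessage(e))
        })
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- do.call(rbind, rows)
  for (th in thresholds) {
    out[[sprintf("sig_%g", th)]] <- !is.na(out$p) & out$p < th
  }
  out <- out[order(out$trait, out$p, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  nTests <- sum(is.na(out$skipped))
  attr(out, "expected_false_positives") <-
    setNames(nTests * thresholds, sprintf("p<%g", thresholds))
  out
}
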