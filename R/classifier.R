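## Scaffold contamination screen: class-conditional bivariate Gaussians on
## (GC fraction, log10 mean coverage), posterior retention rule p > 0.2,
## with a homology-label override.

#' Profile scaffolds by GC content and mean coverage
#'
#' GC is computed over ACGT bases only (N excluded from the denominator).
#' Scaffolds missing from the coverage table get `NA` coverage and are
#' excluded from classification, with a message.
#'
#' @param fasta `DNAStringSet` (or FASTA path) of scaffolds.
#' @param coverage data.frame (seqid, coverage) of mean per-base depth, or
#'   a named numeric vector.
#' @param homology_labels optional named character seqid -> "target" /
#'   "contaminant" (e.g. from BLAST); defaults to "none".
#' @return data.frame of class `scaffold_profiles`: scaffold, length,
#'   gc_fraction, mean_coverage, homology_label.
#' @export
profile_scaffolds <- function(fasta, coverage, homology_labels = NULL) {
  if (is.character(fasta) && length(fasta) == 1 && file.exists(fasta))
    fasta <- read_fasta(fasta)
  if (!methods::is(fasta, "DNAStringSet")) fasta <- Biostrings::DNAStringSet(fasta)
  if (is.null(names(fasta))) stop("scaffolds must be named")
  freq <- Biostrings::alphabetFrequency(fasta, baseOnly = TRUE)
  acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0, (freq[, "C"] + freq[, "G"]) / acgt, NA)
  if (is.data.frame(coverage)) {
    cov <- stats::setNames(coverage$coverage, coverage$seqid)
  } else cov <- coverage
  mean_cov <- unname(cov[names(fasta)])
  if (anyNA(mean_cov))
    message(sum(is.na(mean_cov)),
            " scaffold(s) missing from coverage track; excluded from classification")
  lab <- rep("none", length(fasta))
  names(lab) <- names(fasta)
  if (!is.null(homology_labels)) {
    bad <- setdiff(homology_labels, c("target", "contaminant", "none"))
    if (length(bad)) stop("homology labels must be target/contaminant/none")
    lab[names(homology_labels)] <- homology_labels
  }
  out <- data.frame(scaffold = names(fasta),
                    length = Biostrings::width(fasta),
                    gc_fraction = gc,
                    mean_coverage = mean_cov,
                    homology_label = unname(lab),
                    stringsAsFactors = FALSE)
  class(out) <- c("scaffold_profiles", "data.frame")
  out
}

.mvn_logdens <- function(x, mu, sigma) {
  # bivariate normal log density; x is an n x 2 matrix
  d <- sweep(x, 2, mu)
  inv <- solve(sigma)
  q <- rowSums((d %*% inv) * d)
  -log(2 * pi) - 0.5 * log(det(sigma)) - 0.5 * q
}

#' Train the two-class GC/coverage scaffold classifier
#'
#' Fits class-conditional bivariate Gaussians on (GC fraction, log10
#' coverage) with empirical class priors. A degenerate covariance (e.g. all
#' training points identical) is ridge-regularized with a warning.
#'
#' @param profiles `scaffold_profiles` with usable GC and coverage.
#' @param labels character per profile row: "target" or "contaminant"
#'   (>= 5 examples each).
#' @return object of class `scaffold_model`.
#' @export
train_classifier <- function(profiles, labels) {
  stopifnot(nrow(profiles) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% c("target", "contaminant")))
    stop("labels must be 'target' or 'contaminant'")
  if (length(unique(labels)) < 2) stop("need training examples of both classes")
  keep <- !is.na(profiles$gc_fraction) & !is.na(profiles$mean_coverage) &
    profiles$mean_coverage > 0
  profiles <- profiles[keep, , drop = FALSE]; labels <- labels[keep]
  if (any(table(labels) < 5)) stop("need >= 5 labeled examples per class")
  x <- cbind(gc = profiles$gc_fraction, logcov = log10(profiles$mean_coverage))
  fit1 <- function(cl) {
    xi <- x[labels == cl, , drop = FALSE]
    mu <- colMeans(xi)
    sigma <- stats::cov(xi)
    if (!is.finite(det(sigma)) || det(sigma) < 1e-12) {
      warning("degenerate covariance for class '", cl, "'; regularized")
      sigma <- sigma + diag(1e-4, 2)
    }
    list(mu = mu, sigma = sigma, prior = mean(labels == cl))
  }
  structure(list(target = fit1("target"), contaminant = fit1("contaminant")),
            class = "scaffold_model")
}

#' @export
print.scaffold_model <- function(x, ...) {
  cat("scaffold_model (bivariate Gaussian on GC, log10 coverage)\n")
  for (cl in c("target", "contaminant"))
    cat(sprintf("  %s: prior %.2f, mean GC %.3f, mean log10 cov %.2f\n",
                cl, x[[cl]]$prior, x[[cl]]$mu[1], x[[cl]]$mu[2]))
  invisible(x)
}

#' Classify scaffolds and apply the retention rule
#'
#' Computes the posterior probability of target origin for each scaffold
#' and retains scaffolds with posterior above `retain_threshold` (default
#' 0.2) or with a "target" homology label, which overrides a low posterior.
#'
#' @param model a `scaffold_model` from [train_classifier()].
#' @param profiles `scaffold_profiles`.
#' @param retain_threshold retention posterior cutoff (default 0.2).
#' @return the profiles with `posterior_target` and `retained` columns,
#'   plus attributes `n_removed` and `removed_bp`.
#' @export
classify_scaffolds <- function(model, profiles, retain_threshold = 0.2) {
  ok <- !is.na(profiles$gc_fraction) & !is.na(profiles$mean_coverage) &
    profiles$mean_coverage > 0
  post <- rep(NA_real_, nrow(profiles))
  if (any(ok)) {
    x <- cbind(profiles$gc_fraction[ok], log10(profiles$mean_coverage[ok]))
    lt <- .mvn_logdens(x, model$target$mu, model$target$sigma) +
      log(model$target$prior)
    lc <- .mvn_logdens(x, model$contaminant$mu, model$contaminant$sigma) +
      log(model$contaminant$prior)
    mx <- pmax(lt, lc)
    post[ok] <- exp(lt - mx) / (exp(lt - mx) + exp(lc - mx))
  }
  retained <- (!is.na(post) & post > retain_threshold) |
    profiles$homology_label == "target"
  out <- profiles
  out$posterior_target <- post
  out$retained <- retained
  attr(out, "n_removed") <- sum(!retained)
  attr(out, "removed_bp") <- sum(out$length[!retained])
  out
}
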