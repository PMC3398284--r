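#' Read gene sets from a GMT file
#'
#' One set per line: set id, description, then member gene ids, all
#' tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; each has a `description`
#'   attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) next
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    attr(members, "description") <- parts[2]
    sets[[parts[1]]] <- members
  }
  sets
}

#' Logistic-regression gene-set enrichment over FCC' values
#'
#' For each gene set, fits a logistic regression of set membership on the
#' standardised per-gene FCC' and reports the coefficient, Wald P-value and
#' odds ratio per standard deviation of FCC'. A positive coefficient means
#' the set is enriched among haploproficient (fast-growing) genes, a
#' negative one among haploinsufficient genes. BH FDR is computed across all
#' tested sets. Unscored genes are dropped from the universe and from every
#' set; members outside the universe are dropped with a warning.
#'
#' Perfect separation (set membership fully determined by the score) is
#' flagged, and the affected set is refitted with a lightly ridge-penalised
#' logistic regression so a finite coefficient and Wald P are still reported.
#'
#' @param scores Named numeric vector of per-gene FCC' values; names are
#'   gene ids and define the universe.
#' @param sets Named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param min_size Minimum scored members required to test a set.
#' @param ontology Optional named character vector (per set id) carrying an
#'   ontology class label (MF/BP/CC or user-defined).
#' @return An `enrichment_result` data frame: `set_id`, `set_name`,
#'   `ontology`, `n_genes`, `coeff`, `odds_ratio` (= exp(coeff)), `p_value`,
#'   `fdr`, `separation`.
#' @export
lr_enrichment <- function(scores, sets, min_size = 3, ontology = NULL) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("empty universe", call. = FALSE)
  if (is.null(names(scores))) stop("scores must be named by gene id",
                                   call. = FALSE)
  if (stats::sd(scores) == 0) stop("scores have zero variance", call. = FALSE)
  z <- as.numeric(scale(scores))
  genes <- names(scores)
  rows <- list()
  dropped <- 0L
  for (sid in names(sets)) {
    members <- sets[[sid]]
    outside <- setdiff(members, genes)
    dropped <- dropped + length(outside)
    members <- intersect(members, genes)
    if (length(members) < min_size || length(members) >= length(genes)) next
    y <- as.integer(genes %in% members)
    fit <- suppressWarnings(stats::glm(y ~ z, family = stats::binomial()))
    sep <- !fit$converged ||
      any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8)
    if (sep) {
      rf <- ridge_logistic(z, y, lambda = 1e-2)
      beta <- rf$beta; se <- rf$se
    } else {
      sm <- summary(fit)$coefficients
      beta <- sm["z", 1]; se <- sm["z", 2]
    }
    p <- 2 * stats::pnorm(-abs(beta / se))
    rows[[sid]] <- data.frame(
      set_id = sid,
      set_name = attr(sets[[sid]], "description") %||% sid,
      ontology = if (!is.null(ontology)) ontology[[sid]] %||% NA_character_
                 else NA_character_,
      n_genes = length(members), coeff = beta, odds_ratio = exp(beta),
      p_value = p, separation = sep, stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    warning(dropped, " set member(s) absent from the scored universe were ",
            "dropped")
  if (length(rows) == 0)
    return(data.frame(set_id = character(), set_name = character(),
                      ontology = character(), n_genes = integer(),
                      coeff = numeric(), odds_ratio = numeric(),
                      p_value = numeric(), fdr = numeric(),
                      separation = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr <- bh_fdr(res$p_value)
  res <- res[, c("set_id", "set_name", "ontology", "n_genes", "coeff",
                 "odds_ratio", "p_value", "fdr", "separation")]
  class(res) <- c("enrichment_result", "data.frame")
  res
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# ridge-penalised logistic regression (intercept unpenalised) by IRLS;
# fallback for perfectly separated sets
ridge_logistic <- function(z, y, lambda = 1e-2, maxit = 100, tol = 1e-10) {
  X <- cbind(1, z)
  beta <- c(stats::qlogis(max(mean(y), 1e-6)), 0)
  P <- diag(c(0, lambda))
  for (i in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X, X * w) + P
    g <- crossprod(X, y - mu) - P %*% beta
    step <- solve(H, g)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  eta <- as.numeric(X %*% beta)
  mu <- stats::plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  cov <- solve(crossprod(X, X * w) + P)
  list(beta = beta[2], se = sqrt(cov[2, 2]))
}

#' Exact hypergeometric overlap test
#'
#' Tail probability for the overlap `k` between a sample of size `n` and a
#' category of size `K` drawn from a universe of size `N`. `tail = "upper"`
#' gives the enrichment probability P(X >= k); `tail = "lower"` gives the
#' depletion probability P(X <= k).
#'
#' @param k Observed overlap count.
#' @param n Sample-set size.
#' @param K Category size.
#' @param N Universe size.
#' @param tail `"upper"` (enrichment) or `"lower"` (depletion).
#' @return The exact tail probability.
#' @examples
#' hypergeom_overlap(31, 123, 1932, 5713, tail = "lower")
#' @export
hypergeom_overlap <- function(k, n, K, N, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K))
    stop("inconsistent counts: need 0 <= k <= min(n, K) <= N and n, K <= N",
         call. = FALSE)
  if (tail == "lower") stats::phyper(k, K, N - K, n)
  else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' HI/HP frequencies per category with hypergeometric tests
#'
#' Given per-gene HFC classes and a per-gene category partition, tabulates
#' the number and percentage of HI and HP genes in each category and tests
#' each category's HI (and HP) count against the universe-wide frequency with
#' exact hypergeometric tails (depletion = lower, enrichment = upper).
#' Genes with class `NA` are dropped. The two inputs must be named by gene
#' id and cover the same genes.
#'
#' @param classes Named character vector of per-gene classes
#'   (HI/HP/NS, NA allowed).
#' @param partition Named character vector of per-gene category labels.
#' @return A data frame with one row per category: `category`, `n`, `n_hi`,
#'   `n_hp`, `pct_hi`, `pct_hp`, `p_hi_deplete`, `p_hi_enrich`,
#'   `p_hp_deplete`, `p_hp_enrich`, plus attributes `universe_n`,
#'   `universe_pct_hi`.
#' @export
class_frequency_table <- function(classes, partition) {
  if (is.null(names(classes)) || is.null(names(partition)))
    stop("classes and partition must be named by gene id", call. = FALSE)
  only_c <- setdiff(names(classes), names(partition))
  only_p <- setdiff(names(partition), names(classes))
  if (length(only_c) || length(only_p))
    stop("gene ids do not align; classes-only: [",
         paste(utils::head(only_c, 5), collapse = ", "),
         "] partition-only: [",
         paste(utils::head(only_p, 5), collapse = ", "), "]", call. = FALSE)
  partition <- partition[names(classes)]
  keep <- !is.na(classes)
  classes <- classes[keep]; partition <- partition[keep]
  N <- length(classes)
  K_hi <- sum(classes == "HI"); K_hp <- sum(classes == "HP")
  cats <- sort(unique(partition))
  rows <- lapply(cats, function(cat) {
    in_cat <- partition == cat
    n <- sum(in_cat)
    k_hi <- sum(classes[in_cat] == "HI")
    k_hp <- sum(classes[in_cat] == "HP")
    data.frame(category = cat, n = n, n_hi = k_hi, n_hp = k_hp,
               pct_hi = 100 * k_hi / n, pct_hp = 100 * k_hp / n,
               p_hi_deplete = hypergeom_overlap(k_hi, n, K_hi, N, "lower"),
               p_hi_enrich  = hypergeom_overlap(k_hi, n, K_hi, N, "upper"),
               p_hp_deplete = hypergeom_overlap(k_hp, n, K_hp, N, "lower"),
               p_hp_enrich  = hypergeom_overlap(k_hp, n, K_hp, N, "upper"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "universe_n") <- N
  attr(out, "universe_pct_hi") <- 100 * K_hi / N
  out
}
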