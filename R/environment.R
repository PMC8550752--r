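#' Configuration for the model's semantic environment
#'
#' The environment holds hierarchically structured binary "visual" patterns
#' and three-tier "verbal" label patterns for a set of simulated objects.
#' Items are organised as domains (superordinate, e.g. animals / objects /
#' plants), each containing several categories (basic level), each containing
#' several items (subordinate level). Visual patterns are built by
#' distortion of prototypes: a random domain prototype, a category prototype
#' obtained by flipping each domain-prototype bit with probability
#' `flip_prob_category`, and item vectors obtained by flipping category
#' prototype bits with probability `flip_prob_item`. This makes items from
#' the same category share many properties and items from the same domain
#' share a few.
#'
#' @param n_domains Number of domains (default 3).
#' @param n_categories_per_domain Categories per domain (default 3).
#' @param n_items_per_category Items per category (default 10).
#' @param n_visual_bits Length of each item's binary visual pattern
#'   (default 48).
#' @param flip_prob_category Probability that a domain-prototype bit is
#'   flipped (complemented) to form a category prototype. Must lie in
#'   `[0, 0.5)`.
#' @param flip_prob_item Probability that a category-prototype bit is flipped
#'   to form an individual item. Must lie in `[0, 0.5)`.
#' @param seed RNG seed; regenerating with the same seed reproduces the
#'   matrices bit for bit.
#'
#' @return An object of class `env_config`.
#' @export
env_config <- function(n_domains = 3L, n_categories_per_domain = 3L,
                       n_items_per_category = 10L, n_visual_bits = 48L,
                       flip_prob_category = 0.15, flip_prob_item = 0.05,
                       seed = 1L) {
  counts <- c(n_domains = n_domains, n_categories_per_domain = n_categories_per_domain,
              n_items_per_category = n_items_per_category, n_visual_bits = n_visual_bits)
  if (any(counts < 1) || any(counts != round(counts)))
    stop("all counts must be integers >= 1")
  for (p in c(flip_prob_category, flip_prob_item))
    if (!is.finite(p) || p < 0 || p >= 0.5)
      stop("flip probabilities must lie in [0, 0.5)")
  structure(list(
    n_domains = as.integer(n_domains),
    n_categories_per_domain = as.integer(n_categories_per_domain),
    n_items_per_category = as.integer(n_items_per_category),
    n_visual_bits = as.integer(n_visual_bits),
    flip_prob_category = flip_prob_category,
    flip_prob_item = flip_prob_item,
    seed = as.integer(seed)
  ), class = "env_config")
}

#' Generate the semantic environment
#'
#' Builds the binary visual matrix and the three-tier verbal label matrix.
#' Each verbal row has exactly three active units: one superordinate (domain)
#' label shared by all items in the domain, one basic-level (category) label
#' shared within the category, and one subordinate label unique to the item.
#'
#' @param config An [env_config()].
#'
#' @return An object of class `env_spec`: a list with elements
#'   `visual` (items x n_visual_bits 0/1 matrix), `verbal` (items x
#'   (n_domains + n_categories + n_items) 0/1 matrix), `domain_label`,
#'   `category_label`, `item_id` (per-item integer/character vectors) and
#'   the `config`.
#' @export
generate_environment <- function(config = env_config()) {
  stopifnot(inherits(config, "env_config"))
  n_dom <- config$n_domains
  n_cat <- config$n_categories_per_domain
  n_itm <- config$n_items_per_category
  nb <- config$n_visual_bits
  n_categories <- n_dom * n_cat
  n_items <- n_categories * n_itm

  set.seed(config$seed)

  flip <- function(proto, p) {
    # deterministic complement of the sampled bit positions
    mask <- stats::runif(length(proto)) < p
    ifelse(mask, 1L - proto, proto)
  }

  visual <- matrix(0L, n_items, nb)
  domain_label <- integer(n_items)
  category_label <- integer(n_items)
  row <- 0L
  for (d in seq_len(n_dom)) {
    dom_proto <- as.integer(stats::runif(nb) < 0.5)  # i.i.d. Bernoulli(0.5)
    for (cc in seq_len(n_cat)) {
      cat_proto <- flip(dom_proto, config$flip_prob_category)
      for (i in seq_len(n_itm)) {
        row <- row + 1L
        visual[row, ] <- flip(cat_proto, config$flip_prob_item)
        domain_label[row] <- d
        category_label[row] <- (d - 1L) * n_cat + cc
      }
    }
  }

  verbal <- matrix(0L, n_items, n_dom + n_categories + n_items)
  for (r in seq_len(n_items)) {
    verbal[r, domain_label[r]] <- 1L
    verbal[r, n_dom + category_label[r]] <- 1L
    verbal[r, n_dom + n_categories + r] <- 1L
  }

  structure(list(
    visual = visual, verbal = verbal,
    domain_label = domain_label, category_label = category_label,
    item_id = seq_len(n_items), config = config
  ), class = "env_spec")
}

#' Summarise the visual similarity structure of an environment
#'
#' Computes mean pairwise visual similarity (proportion of matching bits,
#' i.e. 1 - normalised Hamming distance) at three levels: within category,
#' within domain but across categories, and across domains, together with a
#' flag indicating whether the intended ordering
#' within-category > within-domain > cross-domain holds.
#'
#' @param env An `env_spec`.
#' @return A list with `within_category`, `within_domain`, `cross_domain`
#'   (scalar means) and `ordering_holds` (logical).
#' @export
similarity_report <- function(env) {
  stopifnot(inherits(env, "env_spec"))
  v <- env$visual
  nb <- ncol(v)
  # pairwise proportion of matching bits
  agree <- (tcrossprod(v) + tcrossprod(1 - v)) / nb
  same_cat <- outer(env$category_label, env$category_label, "==")
  same_dom <- outer(env$domain_label, env$domain_label, "==")
  up <- upper.tri(agree)
  list(
    within_category = mean(agree[up & same_cat]),
    within_domain = mean(agree[up & same_dom & !same_cat]),
    cross_domain = mean(agree[up & !same_dom]),
    ordering_holds = {
      wc <- mean(agree[up & same_cat]); wd <- mean(agree[up & same_dom & !same_cat])
      cd <- mean(agree[up & !same_dom]); wc > wd && wd > cd
    }
  )
}

#' Write / read an environment as TSV plus a JSON sidecar
#'
#' The TSV holds one row per item: `item_id`, `domain`, `category`, then the
#' visual bits (`v1..vK`) and the verbal bits (`w1..wL`). The sidecar
#' (`<path>.json`) stores the generating configuration including the seed.
#'
#' @param env An `env_spec`.
#' @param path Path of the TSV file to write.
#' @return `path`, invisibly.
#' @export
write_environment <- function(env, path) {
  stopifnot(inherits(env, "env_spec"))
  df <- data.frame(item_id = env$item_id, domain = env$domain_label,
                   category = env$category_label)
  vis <- as.data.frame(env$visual); names(vis) <- paste0("v", seq_len(ncol(vis)))
  verb <- as.data.frame(env$verbal); names(verb) <- paste0("w", seq_len(ncol(verb)))
  utils::write.table(cbind(df, vis, verb), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(env$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_environment
#' @export
read_environment <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  cfgl <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  config <- do.call(env_config, cfgl)
  vcols <- grep("^v[0-9]+$", names(df))
  wcols <- grep("^w[0-9]+$", names(df))
  structure(list(
    visual = as.matrix(df[, vcols]), verbal = as.matrix(df[, wcols]),
    domain_label = df$domain, category_label = df$category,
    item_id = df$item_id, config = config
  ), class = "env_spec")
}
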