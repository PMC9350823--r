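#' Build task catalogs with a linear difficulty ladder
#'
#' Each therapy domain exposes an ordered inventory of task levels, ranked
#' serially from least to most difficult (the domain's progression order).
#' The simulator represents a domain by consecutive ranks `1..L` with a
#' strictly increasing difficulty scalar per rank; here difficulty is linear
#' in rank, `delta_r = r * difficulty_step`.
#'
#' @param n_domains number of domains to create (>= 1).
#' @param L number of task levels per domain (>= 2).
#' @param difficulty_step increment in difficulty between consecutive ranks
#'   (> 0), on the same latent scale as patient ability.
#' @param domain_ids optional character vector of domain labels; defaults to
#'   `"domain01"`, `"domain02"`, ...
#' @return a named list of `task_catalog` objects, each a list with
#'   `domain_id`, `ranks` (1..L) and `difficulty` (increasing numeric).
#' @examples
#' cats <- make_task_catalog(2, L = 5, difficulty_step = 1)
#' cats[[1]]$difficulty
#' @export
make_task_catalog <- function(n_domains, L, difficulty_step = 0.5,
                              domain_ids = NULL) {
  n_domains <- check_count(n_domains, "n_domains", lower = 1)
  L <- check_count(L, "L", lower = 2)
  check_scalar_number(difficulty_step, "difficulty_step")
  if (difficulty_step <= 0) stop_invalid("difficulty_step must be > 0")
  if (is.null(domain_ids)) {
    domain_ids <- sprintf("domain%02d", seq_len(n_domains))
  }
  if (length(domain_ids) != n_domains) {
    stop_invalid("domain_ids must have length n_domains")
  }
  cats <- lapply(domain_ids, function(id) {
    structure(
      list(domain_id = id,
           ranks = seq_len(L),
           difficulty = seq_len(L) * difficulty_step),
      class = "task_catalog")
  })
  names(cats) <- domain_ids
  cats
}

is_task_catalog <- function(x) inherits(x, "task_catalog")

catalog_L <- function(catalog) {
  if (!is_task_catalog(catalog)) stop_invalid("not a task_catalog")
  length(catalog$ranks)
}
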