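#' Stratified permuted-block 1:1 randomization
#'
#' Allocates a sequence of arrivals to two arms within strata using
#' permuted blocks. Each time a stratum's queue empties, a new block is
#' created: its size is drawn uniformly at random from `block_sizes` and
#' its balanced arm sequence is randomly permuted. Within every completed
#' block the arms are exactly balanced, and the running per-stratum
#' imbalance never exceeds `max(block_sizes) / 2`.
#'
#' The audit log records arrival order, stratum, block and arm. The
#' redacted view, suitable for site staff who must remain masked to the
#' biopsy pathotype, omits the stratum and block columns.
#'
#' @param stratum character/factor of stratum labels in arrival order
#'   (e.g. `pathotype x site` via [make_stratum()]).
#' @param block_sizes permissible block sizes (even, default `c(6, 4)`).
#' @param arms the two arm labels.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return List with `assignments` (factor, arrival order), `audit`
#'   (`data.frame`: order, stratum, block, arm) and `redacted`
#'   (order and arm only).
#' @export
block_randomize <- function(stratum, block_sizes = c(6, 4),
                            arms = c("rituximab", "tocilizumab"),
                            seed = NULL) {
  if (length(stratum) == 0) stop("empty arrival sequence")
  if (length(arms) != 2) stop("exactly two arms are supported")
  if (any(block_sizes %% 2 != 0) || any(block_sizes < 2))
    stop("block sizes must be even and at least 2")
  if (!is.null(seed)) set.seed(seed)
  stratum <- as.character(stratum)
  queues <- list()
  block_no <- list()
  n <- length(stratum)
  arm_out <- character(n)
  block_out <- integer(n)
  for (i in seq_len(n)) {
    s <- stratum[i]
    q <- queues[[s]]
    if (is.null(q) || length(q) == 0) {
      bs <- if (length(block_sizes) == 1) block_sizes else
        sample(block_sizes, 1)
      q <- sample(rep(arms, bs / 2))
      block_no[[s]] <- if (is.null(block_no[[s]])) 1L else block_no[[s]] + 1L
    }
    arm_out[i] <- q[1]
    block_out[i] <- block_no[[s]]
    queues[[s]] <- q[-1]
  }
  audit <- data.frame(order = seq_len(n), stratum = stratum,
                      block = block_out, arm = arm_out,
                      stringsAsFactors = FALSE)
  list(assignments = factor(arm_out, levels = arms),
       audit = audit,
       redacted = audit[, c("order", "arm")])
}

#' Combined randomization stratum label
#'
#' The trial stratified by histology pathotype crossed with site group
#' (lead centre versus all other sites).
#'
#' @param pathotype pathotype labels.
#' @param site site-group labels.
#' @return Character vector `pathotype:site`.
#' @export
make_stratum <- function(pathotype, site) {
  paste(as.character(pathotype), as.character(site), sep = ":")
}
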