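#' Build the landmark super dataset
#'
#' For each landmark `s` in the design grid, selects the subjects still at
#' risk at `s` (observed time strictly greater than `s` — the
#' left-truncation convention), truncates their follow-up at the horizon
#' `s + w` by administrative censoring, and stacks the per-landmark data
#' sets with a stratum label. An event is retained only if it happened
#' inside the window `(s, s + w]`; events exactly at the horizon count
#' (closed right endpoint), censoring at the horizon is applied after.
#' Basis-expanded interaction columns `cov.fj = x * f_j(s)` and landmark
#' columns `gj = g_j(s)` are appended so both supermodels are plain Cox
#' fits over this one data frame.
#'
#' @param cohort data frame with `id`, `time`, `status` and covariates
#' @param design a [landmark_design]
#' @param columns covariate columns to carry (default: all)
#' @return data frame of class `dl_superdata` with columns `id`,
#'   `stratum_s`, `entry`, `exit`, `status`, the original covariates, then
#'   `cov.f1, cov.f2, ..., g1, g2, ...`; the design travels as an attribute
#' @export
build_landmark_dataset <- function(cohort, design, columns = NULL) {
  stopifnot(inherits(design, "landmark_design"))
  df <- as.data.frame(cohort)
  if (!nrow(df)) stop("cohort is empty")
  if (is.null(columns)) columns <- cohort_columns(df)
  w <- design$w
  empty <- design$grid[vapply(design$grid, function(s) !any(df$time > s), logical(1))]
  if (length(empty))
    stop("no subjects at risk at landmark(s): ",
         paste(format(empty), collapse = ", "))
  pieces <- lapply(design$grid, function(s) {
    at_risk <- df$time > s
    sub <- df[at_risk, , drop = FALSE]
    exit <- pmin(sub$time, s + w)
    status <- as.integer(sub$status == 1 & sub$time <= s + w)
    out <- data.frame(id = sub$id, stratum_s = s, entry = s,
                      exit = exit, status = status)
    for (cl in columns) out[[cl]] <- sub[[cl]]
    fs <- drop(eval_basis(design$f_basis, s))
    for (j in seq_along(design$f_basis))
      for (cl in columns)
        out[[paste0(cl, ".f", j)]] <- sub[[cl]] * fs[j]
    gs <- drop(eval_basis(design$g_basis, s))
    for (j in seq_along(design$g_basis))
      out[[paste0("g", j)]] <- gs[j]
    out
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  # row-count identity: one row per (subject still at risk, landmark)
  stopifnot(nrow(res) == sum(vapply(design$grid,
                                    function(s) sum(df$time > s), numeric(1))))
  attr(res, "design") <- design
  attr(res, "covariates") <- columns
  class(res) <- c("dl_superdata", "data.frame")
  res
}

# expanded interaction column names for a superdata
superdata_fcols <- function(covariates, nf) {
  if (!length(covariates)) return(character(0))
  as.vector(t(outer(covariates, seq_len(nf),
                    function(cl, j) paste0(cl, ".f", j))))
}
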