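# Small shared helpers. Node roles follow the CellNOpt convention:
# stimulated / inhibited / measured are "designated"; everything else is
# "undesignated" and may be compressed away.

ROLE_LEVELS <- c("stimulated", "inhibited", "measured", "undesignated")

check_roles <- function(roles) {
  if (!length(roles)) return(invisible(roles))
  if (is.null(names(roles)) || any(!nzchar(names(roles))))
    stop("roles must be a named character vector (node -> role)")
  bad <- setdiff(unique(roles), ROLE_LEVELS)
  if (length(bad))
    stop("unknown role label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(ROLE_LEVELS, collapse = ", "), ")")
  invisible(roles)
}

is_designated <- function(roles) roles %in% c("stimulated", "inhibited", "measured")

edge_key <- function(source, target) paste(source, target, sep = "\r")

#' Rescale a numeric vector to [0, 1]
#'
#' Plain min-max rescaling offered as a convenience for data that are not yet
#' normalized; the modeling functions expect values in \[0, 1\] and do not
#' normalize on their own.
#'
#' @param x numeric vector.
#' @return `(x - min(x)) / (max(x) - min(x))`; a constant vector maps to 0.5.
#' @export
minmax_normalize <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (r[1] == r[2]) return(rep(0.5, length(x)))
  (x - r[1]) / (r[2] - r[1])
}

#' Binarize activity values
#'
#' @param x numeric vector/matrix of values in \[0, 1\].
#' @param threshold values `>= threshold` map to 1, others to 0 (default 0.5).
#' @return integer 0/1 object of the same shape.
#' @export
binarize <- function(x, threshold = 0.5) {
  out <- ifelse(x >= threshold, 1L, 0L)
  if (is.matrix(x)) dim(out) <- dim(x)
  dimnames(out) <- dimnames(x)
  out
}
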