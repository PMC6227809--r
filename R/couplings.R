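#' Synaptic couplings and thresholds
#'
#' Container for the asymmetric coupling matrix \code{J} (entry \code{J[i, j]}
#' is the field contribution of presynaptic unit \code{j} onto postsynaptic
#' unit \code{i}), the local thresholds \code{theta}, and optional structural
#' metadata: a presynaptic sign constraint (Dale's principle) and a structural
#' connectivity mask (used by the restricted visible-hidden architecture).
#' The diagonal of \code{J} is always zero: units have no self-coupling.
#'
#' @param N Number of units; ignored when \code{J} is supplied.
#' @param convention Binary coding of the units, \code{"pm1"} (\code{-1/+1})
#'   or \code{"zero_one"} (\code{0/1}).
#' @param J Optional initial coupling matrix (N x N); defaults to zeros. The
#'   diagonal is forced to zero.
#' @param theta Optional threshold vector; defaults to zeros.
#' @param sign_mask Optional length-N vector of \code{+1} (excitatory) or
#'   \code{-1} (inhibitory) outgoing-sign labels for each presynaptic unit.
#' @param struct_mask Optional N x N 0/1 matrix; entries where the mask is 0
#'   are structurally absent and are kept at exactly zero by every update.
#' @param visible Optional index vector of visible units; defaults to all
#'   units. The complement is the hidden set, which never receives external
#'   stimulus.
#' @return An object of class \code{"dcm_couplings"}.
#' @examples
#' cp <- couplings(10)
#' dim(cp$J)
#' @export
couplings <- function(N, convention = c("pm1", "zero_one"), J = NULL,
                      theta = NULL, sign_mask = NULL, struct_mask = NULL,
                      visible = NULL) {
  convention <- match.arg(convention)
  if (!is.null(J)) {
    J <- as.matrix(J)
    if (nrow(J) != ncol(J)) stop("`J` must be square", call. = FALSE)
    N <- nrow(J)
  } else {
    J <- matrix(0, N, N)
  }
  diag(J) <- 0
  if (is.null(theta)) theta <- numeric(N)
  if (length(theta) != N) stop("`theta` must have length N", call. = FALSE)
  if (!is.null(sign_mask)) {
    if (length(sign_mask) != N || !all(sign_mask %in% c(-1, 1)))
      stop("`sign_mask` must be a length-N vector of +1/-1", call. = FALSE)
  }
  if (!is.null(struct_mask)) {
    struct_mask <- as.matrix(struct_mask)
    if (!all(dim(struct_mask) == N) || !all(struct_mask %in% c(0, 1)))
      stop("`struct_mask` must be an N x N 0/1 matrix", call. = FALSE)
    diag(struct_mask) <- 0
    J <- J * struct_mask
  }
  if (is.null(visible)) visible <- seq_len(N)
  visible <- sort(unique(as.integer(visible)))
  if (length(visible) < 1L || any(visible < 1L) || any(visible > N))
    stop("`visible` indices out of range", call. = FALSE)
  obj <- structure(list(J = J, theta = as.numeric(theta),
                        sign_mask = sign_mask, struct_mask = struct_mask,
                        convention = convention, visible = visible,
                        hidden = setdiff(seq_len(N), visible)),
                   class = "dcm_couplings")
  validate_couplings(obj)
  obj
}

validate_couplings <- function(x) {
  stopifnot(inherits(x, "dcm_couplings"))
  N <- nrow(x$J)
  if (any(diag(x$J) != 0)) stop("diagonal of J must be zero", call. = FALSE)
  if (length(x$theta) != N) stop("theta length mismatch", call. = FALSE)
  if (!is.null(x$sign_mask)) {
    viol <- sweep(sign(x$J), 2, x$sign_mask, `*`) < 0
    if (any(viol))
      stop("sign constraint violated for ", sum(viol), " synapses",
           call. = FALSE)
  }
  if (!is.null(x$struct_mask) && any(x$J[x$struct_mask == 0] != 0))
    stop("structurally absent synapses must be zero", call. = FALSE)
  invisible(x)
}

n_units <- function(coup) nrow(coup$J)

#' @export
print.dcm_couplings <- function(x, ...) {
  N <- n_units(x)
  cat(sprintf("Couplings for %d %s units", N,
              if (x$convention == "pm1") "+/-1" else "0/1"))
  if (length(x$hidden)) cat(sprintf(" (%d visible, %d hidden)",
                                    length(x$visible), length(x$hidden)))
  cat("\n")
  cat(sprintf("  mean |J| = %.4g, asymmetry |J - t(J)|/|J + t(J)| = %.3f\n",
              mean(abs(x$J)),
              if (any(x$J != 0))
                sum(abs(x$J - t(x$J))) / sum(abs(x$J + t(x$J))) else 0))
  if (!is.null(x$sign_mask))
    cat(sprintf("  Dale sign constraint: %d excitatory, %d inhibitory\n",
                sum(x$sign_mask > 0), sum(x$sign_mask < 0)))
  invisible(x)
}

# apply structural zeros + zero diagonal to an increment matrix
mask_increment <- function(dJ, coup) {
  diag(dJ) <- 0
  if (!is.null(coup$struct_mask)) dJ <- dJ * coup$struct_mask
  dJ
}

#' Project couplings onto the Dale sign constraint
#'
#' Clips to zero every synapse whose sign disagrees with its presynaptic
#' unit's outgoing-sign label, so excitatory columns stay non-negative and
#' inhibitory columns non-positive. Called after every learning update when a
#' \code{sign_mask} is present.
#'
#' @param coup A \code{\link{couplings}} object with a \code{sign_mask}.
#' @return The projected couplings.
#' @export
project_dale <- function(coup) {
  if (is.null(coup$sign_mask))
    stop("`project_dale()` requires couplings with a sign_mask", call. = FALSE)
  viol <- sweep(sign(coup$J), 2, coup$sign_mask, `*`) < 0
  coup$J[viol] <- 0
  coup
}
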