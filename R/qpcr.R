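#' Relative leukocyte telomere length from quantification cycles
#'
#' Efficiency-corrected, calibrator-normalised relative quantification:
#' \deqn{RLTL = E_{TEL}^{Cq_{TEL}(cal) - Cq_{TEL}(s)} /
#'       E_{B2M}^{Cq_{B2M}(cal) - Cq_{B2M}(s)}}
#' where the calibrator ("golden") sample is run on every plate to absorb
#' plate-level measurement error; sample and calibrator must therefore share
#' a plate.  Efficiencies are per-reaction amplification factors in (1, 2]
#' (2 = perfect doubling per cycle), estimated upstream from the raw
#' fluorescence curves.
#'
#' @param sample,calibrator Single plate records: lists/rows with fields
#'   \code{plate_id}, \code{cq_tel}, \code{cq_b2m}, \code{e_tel},
#'   \code{e_b2m}.
#' @return Strictly positive dimensionless ratio.
#' @examples
#' cal <- list(plate_id = "P1", cq_tel = 15, cq_b2m = 20, e_tel = 2, e_b2m = 2)
#' smp <- list(plate_id = "P1", cq_tel = 14, cq_b2m = 20, e_tel = 2, e_b2m = 2)
#' compute_rltl(smp, cal)  # 2: one full doubling cycle fewer for telomere
#' @export
compute_rltl <- function(sample, calibrator) {
  if (!identical(as.character(sample$plate_id),
                 as.character(calibrator$plate_id)))
    stop("sample and calibrator are on different plates (",
         sample$plate_id, " vs ", calibrator$plate_id,
         "); the calibrator corrects plate effects and must be plate-matched")
  e_tel <- as.numeric(sample$e_tel)
  e_b2m <- as.numeric(sample$e_b2m)
  if (any(!is.finite(c(e_tel, e_b2m))) || e_tel <= 0 || e_b2m <= 0)
    stop("amplification efficiencies must be positive")
  e_tel^(as.numeric(calibrator$cq_tel) - as.numeric(sample$cq_tel)) /
    e_b2m^(as.numeric(calibrator$cq_b2m) - as.numeric(sample$cq_b2m))
}

#' RLTL for a whole plate table
#'
#' Applies \code{\link{compute_rltl}} to every non-calibrator record, pairing
#' each with its plate's calibrator.  Every plate must carry exactly one
#' calibrator record.
#'
#' @param plates Data frame of plate records (see
#'   \code{\link{read_plates}}).
#' @return Data frame \code{sample_id, animal_id, plate_id, row_id, rltl}.
#' @export
rltl_table <- function(plates) {
  req <- c("sample_id", "animal_id", "plate_id", "row_id",
           "cq_tel", "cq_b2m", "e_tel", "e_b2m", "is_calibrator")
  miss <- setdiff(req, names(plates))
  if (length(miss)) stop("plate table lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (any(plates$e_tel <= 1 | plates$e_tel > 2 |
          plates$e_b2m <= 1 | plates$e_b2m > 2))
    stop("efficiencies must lie in (1, 2]")
  ncal <- tapply(plates$is_calibrator, plates$plate_id, sum)
  bad <- names(ncal)[ncal != 1L]
  if (length(bad))
    stop("plate(s) without exactly one calibrator: ",
         paste(bad, collapse = ", "))
  out <- lapply(split(plates, plates$plate_id), function(pl) {
    cal <- pl[pl$is_calibrator, , drop = FALSE]
    smp <- pl[!pl$is_calibrator, , drop = FALSE]
    if (!nrow(smp)) return(NULL)
    rl <- vapply(seq_len(nrow(smp)), function(i)
      compute_rltl(smp[i, ], cal[1, ]), numeric(1))
    data.frame(sample_id = smp$sample_id, animal_id = smp$animal_id,
               plate_id = smp$plate_id, row_id = smp$row_id,
               rltl = rl, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(match(out$sample_id, plates$sample_id)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' DNA quality-control gate
#'
#' Pass requires yield > 20 ng/ul, 260/280 ratio > 1.7, 260/230 ratio > 1.8
#' (all strict) and an integrity gel score in [1, 2] (inclusive).  QC never
#' throws: every violated rule is reported as a reason code.
#'
#' @param yield_ng_per_ul,ratio_260_280,ratio_260_230,gel_integrity Numeric
#'   vectors (recycled to a common length).
#' @return Data frame with logical \code{pass} and character \code{reasons}
#'   (comma-joined codes among \code{yield}, \code{ratio_260_280},
#'   \code{ratio_260_230}, \code{gel_integrity}; empty when passing).
#' @export
apply_qc <- function(yield_ng_per_ul, ratio_260_280, ratio_260_230,
                     gel_integrity) {
  n <- max(length(yield_ng_per_ul), length(ratio_260_280),
           length(ratio_260_230), length(gel_integrity))
  y <- rep_len(as.numeric(yield_ng_per_ul), n)
  r28 <- rep_len(as.numeric(ratio_260_280), n)
  r23 <- rep_len(as.numeric(ratio_260_230), n)
  gel <- rep_len(as.numeric(gel_integrity), n)
  fails <- cbind(yield = !(y > 20),
                 ratio_260_280 = !(r28 > 1.7),
                 ratio_260_230 = !(r23 > 1.8),
                 gel_integrity = !(gel >= 1 & gel <= 2))
  fails[is.na(fails)] <- TRUE
  reasons <- apply(fails, 1L, function(f)
    paste(colnames(fails)[f], collapse = ","))
  data.frame(pass = rowSums(fails) == 0L, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Log-transform RLTL and check normality
#'
#' Natural-log transformation of the positive RLTL ratios (the base is a
#' pure scale choice absorbed by the variance components downstream),
#' followed by a Shapiro-Wilk normality check on the transformed values.
#'
#' @param rltl Positive numeric vector; names or a parallel \code{sample_id}
#'   identify offending samples in errors.
#' @param sample_id Optional ids for error messages.
#' @return List with \code{log_rltl} (numeric vector) and \code{normality}
#'   (list \code{statistic}, \code{p_value}, \code{method}; both \code{NA}
#'   with \code{degenerate = TRUE} when the transformed values are constant
#'   or too few).
#' @export
log_transform <- function(rltl, sample_id = names(rltl)) {
  rltl <- as.numeric(rltl)
  if (is.null(sample_id)) sample_id <- as.character(seq_along(rltl))
  bad <- which(!is.finite(rltl) | rltl <= 0)
  if (length(bad))
    stop("non-positive RLTL for sample(s): ",
         paste(utils::head(sample_id[bad], 5L), collapse = ", "))
  lv <- log(rltl)
  degenerate <- length(lv) < 3L || stats::sd(lv) == 0
  if (degenerate) {
    norm <- list(statistic = NA_real_, p_value = NA_real_,
                 method = "shapiro-wilk", degenerate = TRUE)
  } else {
    ## Shapiro-Wilk caps at n = 5000; subsample deterministically above that
    x <- lv
    if (length(x) > 5000L) x <- x[round(seq(1L, length(x), length.out = 5000L))]
    sw <- stats::shapiro.test(x)
    norm <- list(statistic = unname(sw$statistic), p_value = sw$p.value,
                 method = "shapiro-wilk", degenerate = FALSE)
  }
  list(log_rltl = lv, normality = norm)
}
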