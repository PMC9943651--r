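#' Render a combined analysis report (markdown)
#'
#' Assembles the results of the binding and stereochemistry analyses into
#' a human-readable markdown document: one K_D table row per
#' oligo/condition system (value +/- SE, NS decision, outliers removed),
#' one stereo-call row per linkage, and an optional contact summary.
#' A provenance block (package version, seed, configuration hash) is
#' included so a report can be traced to its inputs.
#'
#' @param fits Named list of results from \code{\link{fit_binding}}
#'   (names like \code{"oligo|condition"}). May be empty.
#' @param calls Optional stereo-call data frame from
#'   \code{\link{call_strand}}.
#' @param contacts Optional pocket summary from
#'   \code{\link{summarize_pocket}}.
#' @param seed Seed to record in the provenance block.
#' @param file Optional path; when given the report is also written there.
#' @return The report as a character vector of lines (invisibly when
#'   \code{file} is given).
#' @export
render_report <- function(fits = list(), calls = NULL, contacts = NULL,
                          seed = NA, file = NULL) {
  if (length(fits) == 0 && is.null(calls) && is.null(contacts))
    stop("nothing to report: supply at least one result object")
  out <- c("# PS oligonucleotide binding and stereochemistry report", "")
  cfg <- paste(names(fits), collapse = ","); if (!nzchar(cfg)) cfg <- "-"
  out <- c(out, "## Provenance", "",
           sprintf("- package: psbind %s",
                   as.character(utils::packageVersion("psbind"))),
           sprintf("- seed: %s", seed),
           sprintf("- config hash: %08x",
                   sum(utf8ToInt(cfg)) %% .Machine$integer.max), "")
  if (length(fits)) {
    out <- c(out, "## Binding affinities", "",
             "| system | K_D (uM) | A0 | dA | NS model | outliers removed |",
             "|---|---|---|---|---|---|")
    for (nm in names(fits)) {
      r <- fits[[nm]]
      f <- r$fit
      se <- f$std_errors
      ns_lab <- if (f$ns_model)
        sprintf("NS = %.3g", f$params$ns) else "NS = 0"
      out <- c(out, sprintf(
        "| %s | %.3g +/- %.2g | %.3g | %.3g | %s | %d |",
        nm, f$params$k_d, se[["k_d"]], f$params$a0, f$params$da,
        ns_lab, length(r$outliers)))
    }
    out <- c(out, "")
  }
  if (!is.null(calls) && nrow(calls)) {
    out <- c(out, "## Stereochemistry calls", "",
             "| linkage | residues | call | peak Rp (sigma) | peak Sp (sigma) | mean B (A^2) | reliable |",
             "|---|---|---|---|---|---|---|")
    for (i in seq_len(nrow(calls))) {
      r <- calls[i, ]
      out <- c(out, sprintf("| PS%d | %s-%s | %s | %s | %s | %.1f | %s |",
                            r$linkage_id, r$res5, r$res3, r$call,
                            .fmt_sigma(r$peak_Rp_sigma),
                            .fmt_sigma(r$peak_Sp_sigma),
                            r$b_factor, r$reliable))
    }
    tab <- table(calls$call)
    out <- c(out, "",
             paste("Summary:", paste(sprintf("%s = %d", names(tab), tab),
                                     collapse = ", ")), "")
  }
  if (!is.null(contacts) && nrow(contacts)) {
    out <- c(out, "## PS sulfur contact pocket", "",
             "| residue | hydrophobic contacts | min distance (A) |",
             "|---|---|---|")
    for (i in seq_len(nrow(contacts))) {
      r <- contacts[i, ]
      out <- c(out, sprintf("| %s%d (%s) | %d | %.2f |",
                            r$resname, r$resno, r$chain, r$n_contacts,
                            r$min_distance))
    }
    out <- c(out, "")
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

.fmt_sigma <- function(x) if (is.na(x)) "-" else sprintf("%.1f", x)
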