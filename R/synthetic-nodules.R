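#' Coding schema of the 27 sonographic signs
#'
#' Returns the sign schema of the nodule feature table: for each sign P1..P27
#' its name, kind (continuous or ordinal-coded), the valid sub-feature codes
#' ("Order No" integers), the sub-feature codes regarded as high risk for
#' malignancy, and — for the conditional "if any" signs — the gate that must
#' hold for the sign to apply (conditional signs are coded 0 when their gate
#' is absent, below every defined code).
#'
#' High-risk code sets follow the consensus risk statements for the schema:
#' composition "completely solid" / "solid with <5% microcysts" (P2 codes
#' 1-2); echogenicity "markedly hypoechoic" / "hypoechoic" (P3 codes 2-3);
#' increased anteroposterior/transverse diameter (P4 code 2); ill-defined or
#' irregular edges (P5 codes 1, 3, 4, 5); punctate calcification (P6 code 2);
#' hypoechoic inner echo under incomplete peripheral calcification (P9 code
#' 3); capsule interruption or gross extrathyroidal extension (P14 codes
#' 2-3); microechogenicity in / eccentric solid component of a cystic nodule
#' (P19 codes 2, 4); suspicious or typically metastatic central (P25 codes
#' 5-10) and lateral (P27 codes 2-3) lymph nodes. Signs with no consensus
#' risk direction carry empty high-risk sets.
#'
#' @return A `"sign_schema"` list of 27 entries; each has `notation`, `name`,
#'   `kind`, `codes` (integer vector, ordinal signs only), `high_risk`
#'   (integer vector, possibly empty) and `gate` (NULL, or a list
#'   `list(sign =, codes =)` meaning the sign applies only when the gating
#'   sign's code lies in `codes`).
#' @export
nodule_schema <- function() {
  ord <- function(name, max_code, high_risk = integer(0), gate = NULL)
    list(name = name, kind = "ordinal", codes = seq_len(max_code),
         high_risk = as.integer(high_risk), gate = gate)
  cont <- function(name) list(name = name, kind = "continuous",
                              codes = NULL, high_risk = integer(0),
                              gate = NULL)
  s <- list(
    P1 = cont("Size (mm)"),
    P2 = ord("Composition", 9, high_risk = 1:2),
    P3 = ord("Echogenicity", 9, high_risk = 2:3),
    P4 = ord("Shape (AP/transverse diameter increased)", 2, high_risk = 2),
    P5 = ord("Edge", 8, high_risk = c(1, 3, 4, 5)),
    P6 = ord("Calcification / microechogenicity pattern", 14, high_risk = 2),
    P7 = ord("Distribution of linear microechogenicity", 3,
             gate = list(sign = "P6", codes = 2:14)),
    P8 = ord("Number and distribution of internal microechogenicity", 4,
             gate = list(sign = "P6", codes = 2:14)),
    P9 = ord("Inner echo under incomplete peripheral calcification", 3,
             high_risk = 3, gate = list(sign = "P6", codes = c(8, 10))),
    P10 = cont("AP/horizontal diameter ratio (taller-than-wide)"),
    P11 = ord("Capsule relationship", 9),
    P12 = ord("Perimeter fraction contacting the capsule", 4,
              gate = list(sign = "P11", codes = 2:9)),
    P13 = ord("Abutment of thyroid capsule", 3,
              gate = list(sign = "P11", codes = 2:9)),
    P14 = ord("Interruption in echogenic capsule", 4, high_risk = 2:3,
              gate = list(sign = "P11", codes = 2:9)),
    P15 = ord("Halo", 4),
    P16 = ord("Blood flow pattern", 4),
    P17 = ord("Reflective shadowing in solid nodule", 2),
    P18 = ord("Posterior acoustic enhancement in solid nodule", 2),
    P19 = ord("Solid component features of cystic nodule", 4,
              high_risk = c(2, 4), gate = list(sign = "P2", codes = 2:8)),
    P20 = ord("Localization", 4),
    P21 = ord("Localization within thyroid lobe", 4),
    P22 = ord("Solitary/multinodular", 2),
    P23 = ord("US signs suggesting chronic thyroiditis", 3),
    P24 = ord("Free microechogenicity in the parenchyma", 2),
    P25 = ord("Central lymph node size and features", 10, high_risk = 5:10),
    P26 = ord("Number of central lymph nodes", 3),
    P27 = ord("Lateral metastatic lymph node", 3, high_risk = 2:3)
  )
  for (nm in names(s)) s[[nm]]$notation <- nm
  structure(s, class = "sign_schema")
}

#' @export
print.sign_schema <- function(x, ...) {
  cat(sprintf("Sonographic sign schema: %d signs (%d with high-risk codes)\n",
              length(x),
              sum(vapply(x, function(s) length(s$high_risk) > 0, NA))))
  invisible(x)
}

# class-conditional code distribution of one ordinal sign:
# a (1 - lift) uniform base over all codes, plus lift concentrated on the
# high-risk codes (malignant) or on the complement (benign)
code_probs <- function(sign, malignant, risk_lift) {
  codes <- sign$codes
  base <- rep(1 / length(codes), length(codes))
  hr <- codes %in% sign$high_risk
  if (!any(hr) || risk_lift == 0) return(base)
  extra <- if (malignant) hr / sum(hr) else (!hr) / sum(!hr)
  (1 - risk_lift) * base + risk_lift * extra
}

#' Generate a synthetic labeled nodule table
#'
#' Seeded generator of tables in the 27-sign coding schema, standing in for
#' the undistributed clinical cohort. Labels are fixed by count (default 284
#' malignant / 114 benign of 398, the cohort's class sizes). Each ordinal
#' sign is drawn from a class-conditional categorical distribution: a
#' uniform base over its codes with probability mass `risk_lift` routed to
#' the high-risk codes for malignant nodules and away from them for benign
#' ones, so `risk_lift = 0` makes every sign independent of the label and
#' larger values strengthen the class signal. Nodule size P1 is log-normal
#' (median 12 mm, 0.5 log-units spread, both classes); the diameter ratio
#' P10 is normal with mean 0.85 (benign) or 1.05 (malignant), sd 0.15 — both
#' invented conveniences, as is the whole joint distribution: signs are
#' conditionally independent given the class, which real sonographic data
#' are not. Conditional signs are set to code 0 wherever their gate code is
#' absent.
#'
#' @param schema a [nodule_schema()] (the default).
#' @param n_total number of nodules (default 398).
#' @param n_malignant number labeled malignant (default 284).
#' @param risk_lift class-conditional enrichment strength in `[0, 1]`
#'   (default 0.8).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `NoduleTable` data frame: numeric columns `P1..P27` plus a
#'   `label` factor with levels benign/malignant.
#' @examples
#' tbl <- generate_nodules(seed = 1)
#' table(tbl$label)
#' @export
generate_nodules <- function(schema = nodule_schema(), n_total = 398,
                             n_malignant = 284, risk_lift = 0.8, seed = 1) {
  stopifnot(n_total >= 1, n_malignant >= 0, n_malignant <= n_total,
            risk_lift >= 0, risk_lift <= 1)
  set.seed(seed)
  label <- sample(rep(c("malignant", "benign"),
                      c(n_malignant, n_total - n_malignant)))
  mal <- label == "malignant"

  tbl <- data.frame(row.names = seq_len(n_total))
  for (nm in names(schema)) {
    sg <- schema[[nm]]
    if (sg$kind == "continuous") next
    v <- integer(n_total)
    pm <- code_probs(sg, TRUE, risk_lift)
    pb <- code_probs(sg, FALSE, risk_lift)
    if (any(mal)) v[mal] <- sample(sg$codes, sum(mal), TRUE, pm)
    if (any(!mal)) v[!mal] <- sample(sg$codes, sum(!mal), TRUE, pb)
    tbl[[nm]] <- v
  }
  tbl$P1 <- stats::rlnorm(n_total, meanlog = log(12), sdlog = 0.5)
  tbl$P10 <- pmax(stats::rnorm(n_total, mean = ifelse(mal, 1.05, 0.85),
                               sd = 0.15), 0.05)
  # zero out conditional signs whose gate is absent
  for (nm in names(schema)) {
    g <- schema[[nm]]$gate
    if (is.null(g)) next
    tbl[[nm]][!(tbl[[g$sign]] %in% g$codes)] <- 0L
  }
  tbl <- tbl[paste0("P", 1:27)]
  tbl$label <- factor(label, levels = c("benign", "malignant"))
  tbl
}

#' Read and write nodule tables
#'
#' CSV with header `P1,...,P27,label`. Reading validates against the schema:
#' the exact column set, numeric sign values, ordinal codes within range
#' (with 0 permitted only for conditional signs), and benign/malignant
#' labels; violations name the offending row and sign.
#'
#' @param table a `NoduleTable` data frame.
#' @param path CSV file path.
#' @param schema a [nodule_schema()].
#' @return `write_nodule_table()` returns `path` invisibly;
#'   `read_nodule_table()` the validated data frame.
#' @export
write_nodule_table <- function(table, path) {
  stopifnot(all(c(paste0("P", 1:27), "label") %in% names(table)))
  utils::write.csv(table[c(paste0("P", 1:27), "label")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_nodule_table
#' @export
read_nodule_table <- function(path, schema = nodule_schema()) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- c(paste0("P", 1:27), "label")
  if (!identical(sort(names(tbl)), sort(want))) {
    extra <- setdiff(names(tbl), want)
    missing <- setdiff(want, names(tbl))
    stop("nodule table columns must be exactly P1..P27 and label",
         if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")),
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")))
  }
  tbl <- tbl[want]
  bad_lab <- which(!tbl$label %in% c("benign", "malignant"))
  if (length(bad_lab))
    stop(sprintf("row %d: invalid label '%s'", bad_lab[1],
                 tbl$label[bad_lab[1]]))
  for (nm in paste0("P", 1:27)) {
    sg <- schema[[nm]]
    v <- tbl[[nm]]
    if (!is.numeric(v))
      stop(sprintf("sign %s: values must be numeric", nm))
    if (sg$kind == "ordinal") {
      allowed <- c(if (!is.null(sg$gate)) 0L, sg$codes)
      bad <- which(!(v %in% allowed))
      if (length(bad))
        stop(sprintf("row %d, sign %s: code %s outside the valid range %s",
                     bad[1], nm, format(v[bad[1]]),
                     paste(range(sg$codes), collapse = "..")))
    } else {
      bad <- which(!is.finite(v) | v <= 0)
      if (length(bad))
        stop(sprintf("row %d, sign %s: continuous value must be positive",
                     bad[1], nm))
    }
  }
  tbl$label <- factor(tbl$label, levels = c("benign", "malignant"))
  tbl
}
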