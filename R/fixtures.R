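#' Published regulatory-network fixtures
#'
#' Transcriptions of the published Boolean models used as golden tests:
#' the Drosophila melanogaster segment-polarity subnetwork (15 internal
#' genes, three added control inputs U1-U3), the four-node worked example
#' driven by a single control input, and the T-cell receptor kinetics state
#' table. The same fixtures ship as plain-text files under
#' `inst/extdata/` in the network/problem file formats.
#'
#' @name fixtures
NULL

#' @describeIn fixtures The Drosophila segment-polarity Boolean network:
#'   15 internal nodes with their published update functions and external
#'   control inputs U1 (on ptc), U2 (on wg), U3 (on hh).
#' @return `drosophila_network()`: a [boolean_network()].
#' @export
drosophila_network <- function() {
  boolean_network(
    functions = list(
      SLP = "SLP",
      wg  = "((CIA & SLP & !CIR) | (wg & (CIA | SLP) & !CIR)) & U2",
      WG  = "wg",
      en  = "!SLP",
      EN  = "en",
      hh  = "EN & !CIR & U3",
      HH  = "hh",
      ptc = "CIA & !EN & !CIR & U1",
      PTC = "ptc & PTC",
      PH  = "PTC",
      SMO = "!PTC",
      ci  = "!EN",
      CI  = "ci",
      CIA = "CI & SMO",
      CIR = "CI & !SMO"
    ),
    external = c("U1", "U2", "U3")
  )
}

#' @describeIn fixtures The published control instance on the Drosophila
#'   network: initial and desired expression states with horizon tau = 6.
#' @return `drosophila_problem()`: a [control_problem()].
#' @export
drosophila_problem <- function() {
  control_problem(
    drosophila_network(),
    initial = c(SLP = 0, wg = 1, WG = 1, en = 0, EN = 0, hh = 1, HH = 0,
                ptc = 0, PTC = 0, PH = 0, SMO = 0, ci = 0, CI = 1,
                CIA = 0, CIR = 1),
    desired = c(SLP = 0, wg = 0, WG = 0, en = 1, EN = 1, hh = 0, HH = 1,
                ptc = 0, PTC = 0, PH = 0, SMO = 1, ci = 0, CI = 0,
                CIA = 0, CIR = 0),
    tau = 6
  )
}

#' @describeIn fixtures The four-node worked example: one external input u;
#'   u = 1 forces (v1, v2) to (1, 0) at the next step, u = 0 makes v1 and v2
#'   exchange values; v3 copies v1; v4 is the AND of v2 and v3.
#' @return `fig6_network()`: a [boolean_network()].
#' @export
fig6_network <- function() {
  boolean_network(
    functions = list(
      v1 = "u | (!u & v2)",
      v2 = "!u & v1",
      v3 = "v1",
      v4 = "v2 & v3"
    ),
    external = "u"
  )
}

#' @describeIn fixtures Initial state of the worked example (v1 = v2 = v3 =
#'   0; v4's initial value is unstated in the source and set to 0 — no
#'   golden value depends on it).
#' @return `fig6_initial()`: named bit vector.
#' @export
fig6_initial <- function() c(v1 = 0L, v2 = 0L, v3 = 0L, v4 = 0L)

#' @describeIn fixtures The worked-example control problem: reach v1 = 1,
#'   v2 = 0, v3 = 1 at tau = 3 (v4 unconstrained) — the state produced by
#'   the control sequence u = (1, 0, 0).
#' @return `fig6_problem()`: a [control_problem()].
#' @export
fig6_problem <- function() {
  control_problem(
    fig6_network(),
    initial = fig6_initial(),
    desired = c(v1 = 1, v2 = 0, v3 = 1, v4 = NA),
    tau = 3
  )
}

#' @describeIn fixtures The T-cell receptor kinetics state table: initial
#'   and desired bits for the 40 internal nodes, with the published horizon
#'   tau = 5 attached as an attribute. The network's wiring is published
#'   only as a figure and is deliberately not transcribed; only the state
#'   table is packaged.
#' @return `tcell_states()`: data.frame with columns `node`, `initial`,
#'   `desired` and attribute `tau`.
#' @export
tcell_states <- function() {
  path <- system.file("extdata", "tcell_states.tsv", package = "bncontrol",
                      mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  attr(tab, "tau") <- 5L
  tab
}
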