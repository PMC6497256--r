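---
title: "Exact Boolean network control by SCC decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact Boolean network control by SCC decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bncontrol)
```

## The model

A synchronous Boolean network has internal nodes $v_1,\dots,v_n$, each with
a state $v_i(t)\in\{0,1\}$ and an update rule $f_i$ over AND/OR/NOT; all
nodes update simultaneously from the time-$t$ values. A control problem
adds external nodes $u_1,\dots,u_m$ with no update rule and no incoming
edges: their values are chosen freely at every step. Given an initial state
$v^0$, a desired state $v^\tau$ (possibly with don't-care entries) and a
horizon $\tau$, the task is to find per-step external assignments
$u^0,\dots,u^{\tau-1}$ steering the network into $v^\tau$, or to prove that
none exist. A control sequence holds exactly $\tau$ assignments: a value
chosen at $t=\tau$ cannot influence the state at $\tau$, so a trailing
assignment in input files is accepted and dropped with a warning.

Deciding solvability is NP-hard in general (one can encode satisfiability
in the update rules), so every exact method is exponential somewhere. The
two classical extremes are a brute-force sweep over all $2^{m\tau}$ control
sequences and a backward dynamic program over all $2^n$ states per time
step (the table $D[\text{state},t]$, marked at $\tau$ exactly on the
desired states and propagated backward through the transition map). Both
ship in this package — `brute_force_solve()` and `datta_solve()` — as
baselines and as the cross-checks every solver answer is tested against.

## The decomposition solver

Real regulatory networks are far from fully coupled: their wiring diagrams
break into many small strongly connected components. `solve_control()`
exploits this.

**Reachability tables.** For each node $v$, value $b$ and step $t$ the
solver maintains $\Upsilon^b_v(t)$: can the externals be chosen so that $v$
holds $b$ at $t$, given everything fixed so far? Internal nodes start as a
singleton at $t=0$ (their initial value); unfixed externals have both bits
true at every step. For a node whose inputs' entries at $t$ are known, the
entries at $t+1$ follow by existential quantification over the admissible
input combinations — for an OR node, $\Upsilon^1$ at $t+1$ holds iff some
input has $\Upsilon^1$ at $t$; $\Upsilon^0$ iff all inputs can be 0
simultaneously, and so on through each rule's truth table
(`gamma_simple()`).

**Component categories.** Components are processed in topological order of
the condensation and fall into three classes:

* *simple non-branching* — a single node with at most one outgoing edge to
  the rest of the network. Its per-node table is filled sequentially; if a
  constrained node cannot attain its desired bit at $\tau$, the current
  branch is rejected immediately, before anything downstream is examined.
* *branching single* — one node feeding two or more consumers. Per-node
  tables are no longer sound here: two consumers may each be satisfiable
  on their own but demand contradictory values of the shared ancestor at
  the same step. Such components are therefore *fixed*: their candidate
  value sequences are enumerated and tried one at a time, recursing into
  the remaining components and backtracking on failure.
* *multi-node* — a feedback component of two or more nodes. An embedded
  backward/forward dynamic program computes, per step, the set of component
  states that are forward-reachable from the initial restriction and
  backward-consistent with the horizon restriction, treating the
  already-processed upstream nodes as per-step value sets (singletons for
  fixed trajectories, both values for free externals). Candidate
  trajectories are the paths through the surviving transition edges. The
  forward intersection is an addition over the plain backward table: it
  strictly shrinks the candidate space and cannot remove any true
  trajectory.

A self-loop does not make a singleton component multi-node and does not
count as an outgoing edge for the branching test; the cost of that
convention is handled by the extraction step below.

**Order of enumeration.** Candidates are ordered by the key
$\sum_t s_t\,(2^w)^t$ ($w$ = component width), i.e. counting with $t=0$ as
the least significant digit, so a free external over $\tau=3$ yields the
all-zero sequence first and the sequence $1,0,0,0$ second. The order is
part of the package contract: golden tests and tie-breaking depend on it.
Candidates incompatible with the horizon restriction are filtered during
the component DP, never discovered by backtracking at $t=\tau$.

**Independent work adds.** Weakly connected blocks of the condensation
share nothing, so each is searched on its own; the enumeration counters
over $k$ independent subnetworks grow as $\#S_1+\dots+\#S_k$ rather than
the product a joint state sweep pays. Hard components with condensation
out-degree 0 (leaves) are likewise checked sequentially after the rest is
fixed: nothing depends on them, so each needs only one satisfying candidate
of its own and failures never multiply across leaves. The counters
(`$stats$states_enumerated`, `$stats$candidate_counts`) expose both sides
of this accounting and are asserted in the test suite on a family of
independent chains.

**Extraction and the self-loop subtlety.** Once all components pass, a
concrete sequence is extracted by backward regression: horizon demands on
simple nodes, and the fixed trajectories of hard components, are realized
step by step by choosing admissible input values at $t-1$, posting the
implied demands upstream. Per-node tables can overcount *joint*
reachability across time in exactly one situation: a simple node with a
self-loop, whose value at $t$ and $t+1$ are correlated through its own
update (e.g. $a \leftarrow u \wedge \lnot a$ can hold 1 at two consecutive
steps per-node-wise but never along one trajectory). Extraction is
therefore a complete backtracking search over the input-combination
choices: because every simple node has at most one consumer, demand
cascades from different roots can never collide, the search decomposes
into small independent units, and within a unit the depth-first search over
choices is exhaustive. An unrealizable fixing fails extraction and is
treated like any other failed candidate. A reported "solvable" is always
accompanied by a sequence that passed forward simulation; verification is
unconditional, not a test-only assertion.

**Early rejection.** Before any search, `frozen_nodes()` closes over the
provably constant part of the network: constant rules, input-free nodes,
pure self-copies (pinned to their initial value), and any rule that becomes
constant once its constant inputs are substituted. Each such node carries
the first step from which its value is guaranteed, so a desired value that
contradicts a constant node at the horizon is refused with zero enumeration
— and only when provably correct, since eventually-constant is kept
distinct from frozen-at-all-times.

## Minimal switching

Among valid strategies, `minimize_switching()` returns one minimizing the
number of adjacent-step value flips summed over the externals — the natural
cost when every switch of an intervention is expensive. It runs an exact
dynamic program over (state, previous assignment, step) with cost-to-go =
minimal future switches, then walks forward choosing, at each step, the
lexicographically smallest assignment attaining the optimal residual; the
result is unique, verified, and tested against the brute-force minimum on
random instances. The table has $2^n 2^m$ entries per step, hence its own
size guard (default $n \le 18$).

## Parameters that matter

* `tau` — the horizon, in synchronous steps; all constraint satisfaction is
  *at* $\tau$, not before.
* `max_states` (default $10^7$) and `max_candidates` (default $2^{16}$) —
  resource caps on the search; exceeding one raises a distinct resource
  error rather than returning a wrong decision.
* `max_nodes` guards on the two dynamic programs (22 and 18): the tables
  are exponential in $n$ and the guards are refusals, not truncations;
  `force = TRUE` overrides when memory allows.
* don't-care desired entries (`NA`, `"-"` in files) relax individual nodes
  at the horizon; the per-component DP supports them natively.

## The random-instance generator

`random_instance()` is the synthetic backbone of the test suite. Each
internal node draws its input count from a binomial with `max_inputs`
trials and success probability `edge_density` (zero inputs gives a random
constant), and its rule is a random AND/OR/NOT tree in which every sampled
input genuinely appears, so the dependency graph is exactly the sampled
structure. `target_largest_scc` wires that many nodes into a cycle to
guarantee a multi-node component. The initial state is uniform; with
probability 1/2 the desired state is read off a simulated trajectory under
random controls (guaranteeing solvability), otherwise uniform — so batches
mix solvable and unsolvable instances, which matters when asserting
equivalence of decisions. Instances are byte-reproducible from the seed and
the global RNG state is restored afterwards.

What the generator emulates: sparse wiring, small feedback cores, a
controlled mix of frozen, chain-like and cyclic structure. What it does
not: the degree distributions, canalyzing-function bias and modularity of
curated biological networks, nor their typical sizes. Equivalence of the
three methods on thousands of random instances is therefore evidence of
*correctness of the algorithms*, not a performance claim about real
networks; the packaged Drosophila instance is the biological anchor, and
the suite checks it end to end (decomposition shape, solvability per
horizon, verified sequences, counters).

## Problem sizes used by the tests

The randomized suites run at $n \le 8$, $m \le 2$, $\tau \le 5$ — sizes at
which the brute-force oracle ($\le 2^{10}$ sequences) and the full backward
DP ($\le 2^8$ states) are instant and exhaustive, with 120 instances in the
unit suite and 200 in the acceptance suite; the minimal-switching
comparison enumerates all sequences explicitly on $n \le 5$. The Drosophila
checks run the real instance ($n = 15$, $m = 3$, $\tau = 3..6$; up to
$2^{18}$ sequences for the oracle). These sizes are the package's chosen
trade-off between coverage and a test suite that stays pleasant to run.

## Known limitations

* Worst-case exponential, necessarily: a network that is one big strongly
  connected component degenerates to the full backward DP plus overhead.
* Candidate enumeration materializes path lists; a component with very many
  feasible trajectories hits `max_candidates` and errors out rather than
  streaming.
* The horizon must hold exactly at $\tau$ ("reach at" semantics);
  "reach by" or trajectory avoidance constraints are out of scope.
* Only synchronous, deterministic updates; no probabilistic or asynchronous
  schemes, no attractor analysis.
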