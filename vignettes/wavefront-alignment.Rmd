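---
title: "Gap-affine alignment with bidirectional wavefronts: model, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gap-affine alignment with bidirectional wavefronts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biwfa)
```

## The scoring model

The package aligns a query `q` (length $n$) against a text `t` (length
$m$) globally under gap-affine penalties $(x, o, e)$: a match costs 0, a
mismatch costs $x$, and a gap of length $l$ costs $o + l e$. Penalties
are non-negative integers with $x > 0$ and $e > 0$, so every non-match
operation has positive cost and the optimal score $s$ is a non-negative
integer; no floating point is used anywhere in the engines. There are no
match bonuses and no substitution matrices; sequences are compared
byte-exactly over an arbitrary single-byte alphabet (a CLI flag can
upper-case inputs, the library itself never case-folds).

## Wavefronts

Work happens in the dynamic-programming grid of cells $(v, h)$ ($v$ query
characters and $h$ text characters consumed), indexed by diagonal
$k = h - v$ and *offset* $h$. For each score $s$, component
$c \in \{M, I, D\}$ and diagonal $k$, the wavefront stores the
farthest-reaching offset on $k$ attainable with score $s$ ending in that
component. $M$ ends in a match/mismatch (or a gap closed at no extra
cost), $I$ advances the text only ($k-1 \to k$ at offset $+1$), $D$
advances the query only ($k+1 \to k$, offset unchanged). A new wavefront
follows from those at $s - x$, $s - e$ and $s - o - e$:

$$
\begin{aligned}
I_{s,k} &= \max\{M_{s-o-e,k-1} + 1,\; I_{s-e,k-1} + 1\}\\
D_{s,k} &= \max\{M_{s-o-e,k+1},\; D_{s-e,k+1}\}\\
X_{s,k} &= \max\{M_{s-x,k} + 1,\; I_{s,k},\; D_{s,k}\}\\
M_{s,k} &= X_{s,k} + \mathrm{LCP}\big(q[X_{s,k}-k \dots],\; t[X_{s,k} \dots]\big)
\end{aligned}
$$

with base case $X_{0,0} = 0$. $X$ is materialised transiently into the
$M$ band and never stored. The longest-common-prefix extension is what
makes runs of matches free; it is the only place the sequences are read.
A wavefront depends on at most the previous $p = \max(x, o+e)$
wavefronts — the *scope* — which is why score-only alignment needs just a
ring buffer of $p + 1$ wavefronts. The reverse direction mirrors all of
this with minima, base case $X^{\leftarrow}_{0,m-n} = m$, and
longest-common-suffix extension.

Two conventions are fixed once and guarded by tests:

* **Component-to-CIGAR mapping.** $I$ consumes text only, so it emits the
  SAM-style op `D` (deletion from the query, with the query as the read);
  $D$ consumes query only and emits `I`. The mapping lives in a single
  function; every emitted CIGAR is checked to consume exactly $n$ query
  and $m$ text characters, which would expose any mapping error.
* **Boundary clamping.** A computed offset that would leave the matrix is
  clamped to the boundary cell of its diagonal rather than discarded.
  The farthest-reaching point can sit pinned on the matrix edge while an
  optimal path continues from a cell *behind* it on the same diagonal;
  a boundary-clamped offset is always reachable with at most the current
  score, so the termination test (offset $\ge m$ on diagonal $m - n$)
  and the overlap tests below stay exact. Because clamped offsets carry
  "reachable at $\le s$" rather than "reachable at exactly $s$"
  information, the traceback is a reachability-checked walk (each step
  only requires the predecessor's stored offset to cover the cell the
  path came from, with match > mismatch > $I$ > $D$ and open-before-
  extend preference) backed by a backtracking stack for the rare clamped
  corner cases.

A related observation: per-diagonal offsets at *consecutive* scores are
not monotone in general — for $x > 1$ the wavefront at $s+1$ may reach a
diagonal only through different, shorter paths than the one at $s$. With
unit costs ($x = e = 1$) every cell has a same-diagonal predecessor one
score back and monotonicity holds; the property test asserts it exactly
there, and correctness elsewhere rests on oracle equivalence.

## The bidirectional search

`find_breakpoint()` alternates single score increments, forward then
reverse ($W^\rightarrow_1, W^\leftarrow_1, W^\rightarrow_2, \dots$),
keeping $|s_f - s_r| \le 1$ during the search — comfortably within the
$p$-window the overlap test needs. After each new wavefront, it is
compared against the other direction's retained window of $p$ wavefronts:
on every shared diagonal, the $M$ components overlap when
$M^\rightarrow \ge M^\leftarrow$ (similarly $I$, $D$). An overlap on $M$
witnesses an alignment of total score $s_f + s_r$; on $I$ or $D$ the two
directions have each paid the open of the *same* gap, so the total is
$s_f + s_r - o$. The search keeps the minimum-total candidate and stops
only when no future round can beat it — a later round can only produce
totals of at least $s_f + s_r - o - p + 1$ — so the first candidate is
not necessarily the answer, but the returned one is optimal. As a cheap
shortcut, each direction tracks its farthest antidiagonal ($v + h =
2\,\mathrm{offset} - k$); while the forward maximum is strictly below
the reverse minimum no overlap is possible and the check is skipped.
The shortcut is conservative: an A/B property test asserts the returned
total is identical with it on or off.

The breakpoint cell is taken from the *reverse* offsets (the reverse
farthest-reaching point lies on an optimal traceback), nudged to the
nearest cell where both flanking sub-problems remain realisable: an
$I$-breakpoint needs at least one text character on its left ($h \ge 1$),
a $D$-breakpoint one query character ($v \ge 1$).

## Splitting and boundary conditions

`biwfa_align()` splits $q$ at $v = \mathrm{offset} - k$ and $t$ at the
offset, recursing with boundary components that match the breakpoint
component: the left piece *ends* at it, the right piece *begins* at it.
The open of a gap straddling a breakpoint belongs to the piece containing
the gap's start:

* beginning at $I$/$D$ seeds that component at score 0 (`I_{0,0} = 0`),
  so the first extension costs only $e$ and the gap may close immediately
  at no cost;
* ending at $I$/$D$ keeps the trailing gap's open. In the forward engine
  this is just the end condition ($I_{s,m-n} = m$); in the reverse
  direction — which charges a gap's open at its right end — the indel
  seed enters at score $o$, with no $M$ base at score 0 and no free
  zero-column close at the seed itself (an alignment ending at an indel
  must end with at least one gap column).

The Gotoh oracle implements the same semantics on its three matrices, so
all engines agree on every boundary combination; this is fuzzed directly
in the tests. After both children return, the node re-scores the
assembled piece (a leading gap run matching the begin component waives
its open) and checks it against the breakpoint total; a defensive
fallback re-solves the node directly if they ever disagree — across all
test fuzzing this path is never taken, but it turns any residual
breakpoint corner case into a memory cost rather than a wrong alignment.

Base cases are solved directly by the full-traceback engine when
$\min(n, m) = 0$, $n + m \le 64$, or the breakpoint total is at most
$2p$: such instances are trivially small for the quadratic-memory engine,
and the thresholds guarantee the recursion always makes progress (a
non-progress guard additionally catches a breakpoint that fails to split
the problem). Ties everywhere use a fixed scan order (ascending diagonal,
components $M, I, D$, first minimum kept), so results are deterministic;
any co-optimal alignment is acceptable and only scores are contracted.

The per-node breakpoints are recorded in the result (`$breakpoints`),
letting the tests assert the balance invariant $|s_f - s_r| \le p$ and
the geometric decay $\max(s_f, s_r) \le 2s/3 + p$ at every node — the
bound behind the $O(\log s)$ recursion depth and the overall $O((n+m)s)$
time. Instrumentation counters (cells computed, peak live cells, peak
live wavefronts per direction, recursion depth) are always on; they are
plain integer increments and make the space claim testable: on pairs
simulated at a fixed 10% error rate, doubling the length roughly doubles
the breakpoint search's peak live cells (the suite asserts a factor of at
most 2.2 across 1 kb / 2 kb / 4 kb / 8 kb), while the full-traceback
engine's retained cells grow super-linearly on the same inputs, and the
per-direction window never exceeds $p + 1$ wavefronts.

## The pair generator

`generate_pair()` draws a uniform random text over the profile's alphabet
and derives the query by applying edits: at each text position an event
fires with probability `error_rate`; the event is a mismatch (substituted
with a guaranteed-different character), an insertion, or a deletion, with
default mix 50% / 25% / 25% and geometric indel lengths of mean 2
(support $\ge 1$). The defaults are a generic, moderately indel-rich
read simulator — chosen once as a plausible stand-in for mutation-rate
simulators in this field; they are configurable and recorded in the
profile object. Events falling inside an earlier deletion are dropped,
so the applied-event count is slightly below the binomial expectation at
high error rates. The generator is seeded and byte-reproducible.

What it does *not* emulate: platform-specific error profiles (e.g. the
homopolymer-biased indels of nanopore reads), local repeat structure, or
coverage effects. Passing tests therefore show the engines are exact on
sequences with uniform random errors of the stated rates and lengths —
exactness is a property of the algorithm, not the data, but runtime and
memory profiles on real long reads can differ from the simulated ones.

Test problem sizes are the package's own choice: exhaustive equivalence
on all two-letter pairs of lengths 0–5 under four penalty sets
((1,1,1), (4,5,1), (2,0,1), (3,4,2)); 500 random pairs up to length 300
at error rates up to 40% for the randomized suite (the quadratic oracle
stays comfortable there); 1 kb–8 kb pairs for the space-scaling check.

## Known limitations

* Global alignment only; semi-global/ends-free modes would need different
  initial and termination conditions.
* Single mismatch cost; no piecewise or two-tier gap models.
* The oracle is quadratic — `verify` and `oracle_check` are for modest
  lengths.
* Sequences travel as R character scalars, so embedded NULs are not
  supported and pairs should not contain newline bytes (the readers
  enforce this).

## A minimal session

```{r example}
pen <- affine_penalties(x = 4, o = 5, e = 1)
aln <- biwfa_align("TCTAGCG", "TGGAAAG", pen)
aln$score
aln$cigar
find_breakpoint("TCTAGCG", "TGGAAAG", pen)
```
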