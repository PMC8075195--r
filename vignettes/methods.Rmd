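---
title: "Methods: rule-based schedule-stance and AEFI extraction from forum text"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based schedule-stance and AEFI extraction from forum text}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxforum)
```

## Overview

`vaxforum` determines, from the comments a forum user writes, whether that
user follows the recommended childhood vaccination schedule (RSU) or an
alternative one (ASU), and then characterizes the two groups: their adverse
event following immunization (AEFI) experiences, interests, shared web
domains, geography, and interaction patterns. The design premise is
precision over recall: a rule-based pipeline with hand-auditable patterns
labels fewer comments than a learned classifier would, but each label can be
traced to an explicit syntactic pattern — the property that matters when
user-level labels feed epidemiological association estimates.

## The extraction model

Each comment is split into sentences and each sentence reduced to a
*structured summary*: tokens, lemmas, approximate governor indices, the
subject noun phrase, the main verb (auxiliaries are skipped when a content
verb follows within three tokens), negation cue positions, and, per keyword,
the adjectival and compound modifiers inside its noun phrase. The annotator
is deterministic and rule-based; its vocabulary (verb forms, determiners,
prepositions, a small irregular-lemma table plus plural stripping) covers
the linguistic constructions of the pattern family below. This buys exact
reproducibility — identical input always yields identical labels, with no
model version to pin — at the cost of breadth: summaries of sentences far
outside the pattern family simply have empty subject/verb slots and match
nothing.

The **schedule filter** fires when a schedule keyword (`schedule`,
`spacing`) occurs with its vaccination context established, through one of
three patterns:

* `np_context` — a context term (*vaccination*, *vax*, *shot*, *CDC*, …)
  inside the keyword's noun phrase: "the regular **vaccination** schedule";
* `verb_context` — a vaccination verb governs the clause: "we **vaccinate**
  on the regular schedule";
* `pp_context` — a context term within five tokens after the keyword,
  covering prepositional attachment and objects: "schedule **of
  vaccinations**", "spacing out her **shots**".

Keywords without context ("my work schedule") never match; this
disambiguation step is what keeps the filter's precision high.

The **classifier** labels a matched comment *recommended* by default. The
label flips to *alternative* when an alternative marker (*delayed*,
*selective*, *alternative*, *modified*, *spread-out*, *one-at-a-time*,
*spacing*) appears among the keyword's cues, or when a negation attaches to
the clause verb ("we are **not** vaccinating on the recommended schedule").
A negated alternative cue is a double flip back to *recommended* ("we are
not doing a delayed schedule"). Negation scope is deliberately narrow: a cue
attaches only when it lies within two tokens of a verb candidate in the
same comma-delimited segment as the keyword (or is the keyword's own "no"
determiner), so clause-external negations ("Not sure it matters, but we
follow the regular schedule") do not flip. Within a comment, conflicting
sentence labels resolve alternative-over-recommended: the alternative
markers are the specific signal, the recommended label only a default. All
alternative approaches (delayed, selective, refusal-adjacent) are a single
class; the pattern machinery cannot reliably discriminate among them.

The **AEFI pipeline** is the same machinery with a reaction vocabulary
(fever, seizure, rash, swelling, fussiness, lethargy, vomiting, pain,
developmental regression, plus a generic *reaction* entry) and a
sentence-level immunization-context requirement, so "I have a fever today,
skipping work" is rejected. A comment is a *negative experience* when any
match asserts a non-negated reaction attribution, and a *positive
experience* when every attribution is negated ("no reaction at all after
her 2-month shots") — the rule is monotone toward negative. The
experiencing subject is resolved from the subject noun phrase: first person
→ author; first-person possessive over a child kinship head ("my son") →
child; a possessive chain ("my friend's kid") or other kinship head ("my
nephew") → acquaintance. Both first- and second-hand experiences are kept;
the subject is a recorded field, not a filter.

Both lexica are configuration objects with documented defaults
(`schedule_lexicon()`, `reaction_vocabulary()`, `kinship_table()`) and can
be replaced wholesale, e.g. to port the pipeline to another domain.

## User-level aggregation

Users are labeled from their schedule comments: unanimous labels propagate;
discordant labels resolve by majority; an exact tie resolves to the
chronologically latest comment, on the view that the most recent statement
best reflects current behaviour. The rule is injectable
(`rule = "any_alternative"` is provided as an alternative) because any
conflict rule here is a design choice rather than a forced consequence of
the data. A user reports negative AEFI experiences as soon as one of their
comments does.

The prolificacy curve divides schedule comments into classes $C_{(a,b]}$ by
their author's schedule-comment count and estimates per class the
probability that a comment is labeled *recommended*, with a Wilson 95%
interval (well-behaved near 0 and 1, where the prolific classes live; the
intervals come from `stats::prop.test(correct = FALSE)`). Default class
bounds are powers of two — (0,1], (1,2], (2,4], (4,8], (8,∞) — a standard
choice for heavy-tailed counts. Class sizes partition the labeled comments,
so the class-weighted mean of the per-class probabilities equals the overall
recommended fraction.

Activity statistics per user: authored posts $N_p$, comments $N_c$,
schedule comments $N_{cs}$, the activity period $\tau$ (whole days between
first and last comment; users whose comments all fall on one calendar day
are flagged and excluded from $\tau$ summaries), and the comments received
under each authored post ($I_p$, summarized as a median). $I_p$ is
implemented as comments *received per authored post*; the alternative
reading (comments made per thread) is possible but less consistent with the
interaction-network edge definition, and the choice is documented here.

## Association machinery

All screens use the 2×2 cross-product odds ratio with the Woolf
(log-normal) interval
$\exp\left(\ln \mathrm{OR} \pm z_{1-\alpha/2}\sqrt{1/a + 1/b + 1/c + 1/d}\right)$
and a two-sided Fisher exact p-value (probability-mass definition: the sum
of hypergeometric probabilities not exceeding the observed table's, with
the customary $1+10^{-7}$ tie tolerance). A single zero cell triggers the
Haldane–Anscombe 0.5 correction and is flagged; a zero margin is an error.
Group screening retains groups whose 95% interval excludes 1, with no
multiple-testing correction by default — the per-group confidence-level
criterion is the screening rule being reproduced — and a Benjamini–Hochberg
option for users who want family-wise control.

URL domains default to the full host minus a leading `www.` (so
`pediatrics.aappublications.org` stays informative); a `registrable` mode
collapses to the public-suffix-style registrable domain with a compact
second-level-suffix table. Domains are counted once per comment.

Geolocation resolves a profile's self-reported location first (full state
name, then a trailing two-letter abbreviation), falling back to local group
names ("Texas Moms"); when both signals exist the self-report wins and the
conflict is recorded as `source = "both"`. The precedence is a documented
choice — explicit self-description seems more reliable than group
membership. The 51-row 2010 Census population table ships with the package
for the log–log Pearson correlation between mapped-user counts and state
populations.

Pipeline evaluation follows the two-stage design: filter precision on
retrieved comments, then classifier sensitivity/specificity on the
retrieved, relevant comments with *alternative* (schedule task) or
*negative experience* (AEFI task) as the positive class. Inter-annotator
agreement uses Cohen's $\kappa$ from marginal label frequencies.

## The interaction network

An edge $i \to j$ with weight $w_{ij}$ records that labeled user $i$ wrote
$w_{ij}$ comments under posts authored by labeled user $j$. Self-loops are
excluded: commenting under one's own post is not an inter-user interaction.
Each user gets a leaning (+1 RSU, −1 ASU); the weighted mean leaning of
in-neighbors (users commenting on one's posts) and out-neighbors (authors
one comments on) feed a per-group joint 2D histogram over
$[-1,1]^2$, with 21 bins per axis (odd, so 0 is a bin center). Users with
an undefined side cannot be placed and are excluded; their count is
reported. The directional semantics follow the edge definition literally;
because the natural-language reading of "in-neighbors" is sometimes the
reverse, `neighbor_leaning()` takes an explicit `direction` argument rather
than guessing.

## The synthetic generator

The generator (`generate_corpus()`) is the test bed: it emulates the study
conditions, not the platform. Users draw a latent leaning (ASU with
probability 0.595, matching the reported share among labeled users);
per-user comment counts are the floor of a Pareto variate
($P(N>n) = (n+1)^{1-\alpha}$, $\alpha = 2.5$ — a conventional social-media
activity tail); posts arrive as Poisson(0.4) per user. Each comment
attaches to a post by the homophily process: with probability $h$ the
commenter picks uniformly among same-leaning authors' posts, otherwise
uniformly among all posts, so $h=1$ yields zero cross-leaning edges and
$h=0$ reproduces the population mixture in expectation. Comments carry a
schedule statement with probability 0.35 (phrased via negation with
probability 0.15), an AEFI statement with probability 0.12 (negative with
probability 0.854 for ASUs and 0.748 for RSUs, the reported
negative-experience fractions), a decoy keyword sentence with probability
0.08, and a URL with probability 0.05 from leaning-tilted domain pools.
Public profiles (54%) carry interest-group memberships whose join
probability is logit-shifted by ±0.8 for leaning-aligned groups, a local
state group with probability 0.25, and a self-reported location with
probability 0.62; states are drawn proportional to 2010 Census populations.
Where the emulated study reports no value, these defaults were chosen once
as field-plausible magnitudes and are not tuned.

Sentences are realized from a *template bank* with controlled paraphrase
slots rather than free generation, so the ground-truth label of every
sentence is exact by construction. A configurable fraction of "hard"
templates (double negation, clause-external negation) is flagged in the
ground truth so easy and hard strata can be scored separately. One
consequence of the template design: hard templates with a *recommended*
truth exist (negated alternative cues), but no template realizes an
*alternative* truth through a hard construction, so ASU hard draws fall
back to the negated-recommended phrasing. All randomness flows through one
seeded stream (`withr::with_seed`); identical configurations are
byte-identical on disk.

What passing recovery tests does and does not show: within the template
family, the pipelines recover comment labels essentially perfectly, which
validates the *rule logic* (pattern matching, negation scope, default/flip
classification, aggregation). It does not bound performance on real forum
text, whose paraphrase diversity, typos, sarcasm and topic drift are
outside the generator's scope; on real data the published evaluation design
(`evaluation_metrics()`, `cohen_kappa()` against human annotation) is the
appropriate instrument.

## Numerical and engineering choices

* Corpora are stored as three UTF-8 JSON-lines files (streamable,
  diff-friendly); timestamps are ISO-8601 UTC. Integrity violations are
  data (`integrity_check()` returns descriptions), but loading and writing
  refuse invalid corpora.
* Fisher's test is computed in-package via `dhyper` summation; tests verify
  exact agreement with both `stats::fisher.test` and an independent
  binomial-coefficient enumeration oracle for every table with $N \le 60$.
* Problem sizes in the test suite — 2,000 users for end-to-end recovery,
  5,000 for the activity-tail check, 2,000 null replicates for the
  type-I-error calibration of group screening, 800 users per homophily
  setting — were chosen to make binomial sampling error small relative to
  the tested tolerances while keeping the default suite comfortably
  interactive.
* Missing supplementary detail in the emulated study (exact keyword lists,
  conflict-resolution rule, confidence-interval method, histogram binning)
  is reconstructed with the defaults above; each such reconstruction is
  overridable through configuration so alternatives can be evaluated
  without code changes.

## Known limitations

* English-only, template-scale lexica; porting to another platform or
  language means supplying new lexica and, likely, extending the shallow
  annotator's vocabulary.
* The annotator is not a general dependency parser; long-range attachment,
  coordination and quoted speech are out of scope, consistent with the
  precision-first design.
* The generator's group-membership and URL models are deliberately simple
  (independent memberships, two domain pools); they support association
  screening tests but not, e.g., realistic group co-membership structure.
* User labels are static; temporal opinion change within a user's history
  is not modeled (one label per user, ties to the latest comment).
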