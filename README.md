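# vaxforum

Rule-based text mining of childhood vaccination-schedule adherence from
parenting-forum corpora, in R.

## The problem

A sizeable minority of parents do not follow the recommended childhood
immunization schedule: they delay doses, vaccinate selectively, or spread
shots out. On parenting forums these decisions are stated in plain language
("we do a delayed schedule", "I follow the regular vaccination schedule"),
which makes user-generated content a large-scale, low-cost complement to
surveys for studying vaccine hesitancy. `vaxforum` is a tested, reusable
implementation of an end-to-end pipeline for this task, aimed at
computational epidemiologists and digital-health researchers:

1. **Schedule extraction** — a high-precision filter + classifier that finds
   comments stating the author's scheduling behaviour and labels each
   *recommended* or *alternative*;
2. **AEFI extraction** — the same pattern machinery retargeted at mentions of
   adverse events following immunization (AEFI), recording the experiencing
   subject (author / child / acquaintance) and the reaction named;
3. **User labeling** — aggregation of comment labels to users (RSU =
   recommended-schedule user, ASU = alternative-schedule user), activity
   statistics, and the prolificacy-class curve;
4. **Association screening** — odds ratios with Woolf intervals and Fisher's
   exact test over interest groups, shared URL domains, AEFI experiences and
   geography;
5. **Interaction network** — homophily statistics on the directed weighted
   commenter→post-author graph (echo-chamber diagnostics);
6. **Synthetic corpus generator** — template-realized forum corpora with
   exact per-comment and per-user ground truth, so every stage is testable
   without access to any platform's data.

## The method

The filter parses each sentence into a structured summary (tokens, lemmas,
subject span, main verb, negation cues, and for each keyword its adjectival
and compound modifiers) and matches syntactic patterns of the form

> *I* (subject) *follow* (verb) *the regular* (keyword adjective)
> *vaccination* (keyword compound) *schedule* (target keyword)

A keyword only fires when its vaccination context is established (a context
term inside the keyword's noun phrase or a short window after it, or a
vaccination verb governing the clause), which rejects decoys such as "my
work schedule". The classifier labels matched comments *recommended* by
default and flips to *alternative* on alternative-marker cues (*delayed*,
*selective*, …) or on a negation attached to the governing verb; a negated
alternative cue flips back. Users are labeled by majority over their
schedule comments (exact ties resolve to the latest comment).

Associations between user features and schedule adherence are screened with
the 2×2 odds ratio `OR = ad/bc` and the Woolf interval
`exp(log OR ± z·√(1/a + 1/b + 1/c + 1/d))`, with two-sided Fisher exact
p-values. Network homophily assigns leaning +1 (RSU) / −1 (ASU) and examines
the joint distribution of each user's weighted mean in- and out-neighbor
leanings.

## Worked example

```r
library(vaxforum)

sim   <- generate_corpus(synthetic_config(n_users = 500, seed = 2024))
sim$corpus
#> <forum_corpus> 189 posts, 1122 comments, 500 profiles

sched <- run_schedule_pipeline(sim$corpus)
users <- user_schedule_labels(sched, sim$corpus$comments)
table(users$value)
#> ASU RSU
#> 131 111

aefi   <- run_aefi_pipeline(sim$corpus)
exp_us <- user_experience_labels(aefi)
merged <- merge(users, exp_us, by = "user_id")
t <- table(merged$value.x, merged$value.y)
r <- odds_ratio_ci(contingency_table(
  t["ASU", "reporting_negative"], t["ASU", "reporting_positive"],
  t["RSU", "reporting_negative"], t["RSU", "reporting_positive"]))
sprintf("OR = %.2f, 95%% CI: %.2f-%.2f", r$odds_ratio, r$ci_low, r$ci_high)
#> "OR = 1.39, 95% CI: 0.34-5.75"

g  <- build_graph(sim$corpus, users)
#> <interaction_graph> 242 nodes, 368 edges, total weight 370
jd <- joint_distribution(g, "ASU")
corner_mass(jd)
#> 0.222
```

Reading the output: of the 500 simulated users, 242 wrote at least one
schedule statement and were labeled (131 ASU / 111 RSU — the generator's
ASU share is 0.595 among *all* users, and labeling recovers the mixture
among active ones). The odds ratio measures how much more likely ASUs are
to report a negative AEFI experience than RSUs; at this small corpus size
the interval is wide and crosses 1. The corner mass is the fraction of ASUs
whose in- and out-neighborhoods are both entirely ASU — the echo-chamber
diagnostic, which grows with the generator's homophily parameter.

A thin command-line front end over the same functions is installed at
`inst/cli/vaxforum.R` (subcommands `simulate`, `extract-schedule`,
`extract-aefi`, `label-users`, `associations`, `network`, `run-all`).

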