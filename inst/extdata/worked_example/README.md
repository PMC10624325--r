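# Worked-example cohort fixtures

Generated by `maitrep::worked_example_cohort()` (built literally in code, no
randomness): four donors (HC1, HC2, CD1, CD2), each with a small blood
repertoire (`blood_*.tsv`, AIRR dialect) and a handful of colonic single
cells (`cells.tsv`, wide study dialect).

Hand-computed reference values (all enumerable on paper):

- Simpson clonality, blood, beta-aa clonotypes:
  HC1 counts (4,1,1), N=6: (4·3)/(6·5) = 0.4
  HC2 (2,2), N=4: (2+2)/12 = 1/3
  CD1 (3,1) and CD2 (1,3): 6/12 = 0.5 each
- Morisita-Horn: HC1 vs HC2 = 2·(2/3·1/2)/(1/2 + 1/2) = 2/3;
  CD1 vs CD2 = 2·(3/16)/(10/16 + 10/16) = 0.3
- Public blood sequences: CASSLAPGATNEKLFF in both HC donors (HC-only),
  CASSVDGNTEAFF in both CD donors (CD-only): 2 public, 0 shared.
- Canonical MAIT cells: 11 of 12 (cell c4 uses TRAV8-2 → wrong_trav).
- Colon↔blood overlap (unique colonic CDR3β per stratum / in-blood /
  autologous / allogeneic → integer percents, rounded half away from zero):
  HC 4/3/3/1 → 75/75/25; CD all 4/2/2/1 → 50/50/25;
  CD NC 3/2/2/1 → 67/67/33; CD IC 2/1/1/0 → 50/50/0;
  total 8/5/5/2 → 63/63/25 (5/8 = 62.5% rounds up).
- Sharing edges: HC1 clonotype {c1,c2} → 1 within_HC_biopsy edge;
  CD1 clonotype {d1,d2 inflamed, d3 uninflamed} → 1 within_CD_inflamed and
  2 CD_cross_inflammation edges.
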