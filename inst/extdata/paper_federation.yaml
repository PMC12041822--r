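# Synthetic 6-site federation profile: exact-mode per-site entity x gender cell
# counts. Site totals other than site-5's 2045 are not published anywhere and
# are an arbitrary (documented) split; all nonzero cells are >= 5 except the
# 3 diverse-gender melanoma cases placed at site-1.
entity_map: entity_groups_default.yaml
sites:
  - site_id: site-1
    year: 2022
    mode: exact
    cell_counts:
      prostate: {M: 518}
      breast: {M: 16, W: 416}
      melanoma: {M: 171, W: 141, D: 3}
      lung: {M: 175, W: 92}
      lip_oral_pharynx: {M: 177, W: 76}
      colorectum: {M: 140, W: 87}
      nhl: {M: 90, W: 67}
      cervix: {W: 151}
      pancreas: {M: 68, W: 57}
      thyroid: {M: 35, W: 90}
      bladder: {M: 82, W: 27}
      leukemia: {M: 64, W: 37}
      stomach: {M: 57, W: 30}
      kidney: {M: 57, W: 29}
      uterus: {W: 88}
      brain_cns: {M: 38, W: 31}
      liver: {M: 45, W: 19}
      esophagus: {M: 48, W: 14}
      larynx: {M: 46, W: 8}
      myeloma: {M: 28, W: 23}
      ovary: {W: 52}
      hodgkin: {M: 21, W: 17}
      testis: {M: 37}
      biliary: {M: 17, W: 14}
  - site_id: site-2
    year: 2022
    mode: exact
    cell_counts:
      prostate: {M: 495}
      breast: {W: 397}
      melanoma: {M: 163, W: 135}
      lung: {M: 168, W: 87}
      lip_oral_pharynx: {M: 169, W: 72}
      colorectum: {M: 133, W: 83}
      nhl: {M: 86, W: 64}
      cervix: {W: 145}
      pancreas: {M: 65, W: 55}
      thyroid: {M: 34, W: 86}
      bladder: {M: 78, W: 26}
      leukemia: {M: 61, W: 35}
      stomach: {M: 55, W: 28}
      kidney: {M: 54, W: 28}
      uterus: {W: 84}
      brain_cns: {M: 37, W: 29}
      liver: {M: 43, W: 18}
      esophagus: {M: 46, W: 13}
      larynx: {M: 44, W: 7}
      myeloma: {M: 27, W: 22}
      ovary: {W: 49}
      hodgkin: {M: 20, W: 17}
      testis: {M: 36}
      biliary: {M: 16, W: 14}
  - site_id: site-3
    year: 2022
    mode: exact
    cell_counts:
      prostate: {M: 471}
      breast: {W: 378}
      melanoma: {M: 155, W: 129}
      lung: {M: 160, W: 83}
      lip_oral_pharynx: {M: 161, W: 69}
      colorectum: {M: 127, W: 80}
      nhl: {M: 82, W: 61}
      cervix: {W: 138}
      pancreas: {M: 62, W: 52}
      thyroid: {M: 32, W: 82}
      bladder: {M: 74, W: 25}
      leukemia: {M: 59, W: 34}
      stomach: {M: 52, W: 27}
      kidney: {M: 51, W: 27}
      uterus: {W: 80}
      brain_cns: {M: 35, W: 28}
      liver: {M: 40, W: 18}
      esophagus: {M: 44, W: 12}
      larynx: {M: 42, W: 7}
      myeloma: {M: 26, W: 20}
      ovary: {W: 47}
      hodgkin: {M: 19, W: 16}
      testis: {M: 34}
      biliary: {M: 16, W: 13}
  - site_id: site-4
    year: 2022
    mode: exact
    cell_counts:
      prostate: {M: 401}
      breast: {W: 321}
      melanoma: {M: 132, W: 109}
      lung: {M: 136, W: 71}
      lip_oral_pharynx: {M: 136, W: 59}
      colorectum: {M: 108, W: 68}
      nhl: {M: 69, W: 51}
      cervix: {W: 117}
      pancreas: {M: 52, W: 44}
      thyroid: {M: 27, W: 70}
      bladder: {M: 63, W: 21}
      leukemia: {M: 50, W: 28}
      stomach: {M: 44, W: 23}
      kidney: {M: 44, W: 23}
      uterus: {W: 68}
      brain_cns: {M: 30, W: 24}
      liver: {M: 34, W: 15}
      esophagus: {M: 37, W: 10}
      larynx: {M: 36, W: 6}
      myeloma: {M: 22, W: 17}
      ovary: {W: 40}
      hodgkin: {M: 17, W: 13}
      testis: {M: 29}
      biliary: {M: 13, W: 11}
  - site_id: site-5
    year: 2022
    mode: exact
    cell_counts:
      prostate: {M: 120}
      breast: {W: 100}
      melanoma: {M: 274, W: 226}
      lung: {M: 131, W: 69}
      lip_oral_pharynx: {M: 126, W: 54}
      colorectum: {M: 95, W: 60}
      nhl: {M: 52, W: 38}
      cervix: {W: 30}
      pancreas: {M: 41, W: 34}
      thyroid: {M: 20, W: 50}
      bladder: {M: 49, W: 16}
      leukemia: {M: 38, W: 22}
      stomach: {M: 36, W: 19}
      kidney: {M: 33, W: 17}
      uterus: {W: 20}
      brain_cns: {M: 25, W: 20}
      liver: {M: 28, W: 12}
      esophagus: {M: 31, W: 9}
      larynx: {M: 30, W: 5}
      myeloma: {M: 17, W: 13}
      ovary: {W: 15}
      hodgkin: {M: 14, W: 11}
      testis: {M: 20}
      biliary: {M: 13, W: 12}
  - site_id: site-6
    year: 2021
    mode: exact
    cell_counts:
      prostate: {M: 471}
      breast: {W: 378}
      melanoma: {M: 155, W: 128}
      lung: {M: 160, W: 83}
      lip_oral_pharynx: {M: 161, W: 69}
      colorectum: {M: 127, W: 79}
      nhl: {M: 81, W: 60}
      cervix: {W: 138}
      pancreas: {M: 62, W: 52}
      thyroid: {M: 32, W: 82}
      bladder: {M: 74, W: 25}
      leukemia: {M: 58, W: 34}
      stomach: {M: 52, W: 27}
      kidney: {M: 51, W: 26}
      uterus: {W: 80}
      brain_cns: {M: 35, W: 28}
      liver: {M: 40, W: 18}
      esophagus: {M: 44, W: 12}
      larynx: {M: 42, W: 7}
      myeloma: {M: 25, W: 20}
      ovary: {W: 47}
      hodgkin: {M: 19, W: 16}
      testis: {M: 34}
      biliary: {M: 15, W: 13}
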