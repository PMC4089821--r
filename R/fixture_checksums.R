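# Reference checksums for the packaged Ectateus/Selinus matrix, one per
# taxon row (see row_checksums()); load_ectateus_matrix() refuses a
# fixture whose rows do not reproduce these values.
ectateus_row_checksums <- c(
  Zidalus_latipes = 395L, Lechius_abacoides = 128L,
  Pseudoselinus_punctatostriatus = 790L, Upembarus_upembaensis = 459L,
  Ectateus_crenatus = 2505L, Ectateus_curtulus = 8038L,
  Ectateus_ghesquierei = 2392L, Ectateus_laevistriatus = 2367L,
  Ectateus_lamottei = 2254L, Ectateus_modestus = 2084L,
  Ectateus_ursynowiensis = 1001L, Ectateus_villiersi = 910L,
  Selinus_calcaripes = 1922L, Selinus_convexipennis = 2008L,
  Selinus_gravis = 1866L, Selinus_malaisei = 2372L,
  Selinus_medius = 2372L, Selinus_planus = 1262L,
  Selinus_plicicollis = 2372L, Selinus_striatus = 1262L)
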