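#title: Platynini, southern Levant
#character: id=body_length	kind=numerical	name=Body length	weight=2	group=habitus	units=mm
#character: id=coloration_upperside	kind=categorical	name=Coloration of upper side (head, pronotum, elytra)	weight=2	group=coloration	states=reddish_brown:reddish brown|dark_brown:dark brown|black:black|dark_brown_reddish_margins:dark brown, margins of pronotum and elytra reddish brown|forebody_green_elytra_matt_brown:head and pronotum with green or bluish green metallic luster, elytra matt brown with darkening in central and apical part|blue_to_violet:blue to violet metallic luster|green_coppery_yellow_margin:green and/or coppery with broad yellow elytral margin|elytra_green_forebody_reddish_coppery:elytra green, forebody reddish or coppery|elytra_brownish:elytra brownish|vivid_metallic_green:vivid metallic green|bronze:bronze|dark_brown_to_black:dark brown to black|brown_faint_green_luster:brown with faint green metallic luster
#character: id=metallic_luster	kind=categorical	name=Metallic luster of upper side	weight=2	group=coloration	states=absent:absent|faint:faint|vivid:vivid
#character: id=coloration_legs	kind=categorical	name=Coloration of legs	weight=2	group=coloration	states=reddish_brown:reddish brown|pale_brown_tibiae_darker:femora reddish to pale brown, tibiae darker|brown:brown|dark_tibiae_paler:dark, tibiae (sometimes femora) paler brown
#character: id=first_antennomere	kind=categorical	name=First antennomere	weight=2	group=head	states=trumpet_shaped:apically enlarged behind a small constriction (trumpet-shaped)|regular:regularly shaped
#character: id=labrum	kind=categorical	name=Labrum	weight=2	group=head	states=convex_apex_rounded:clearly convex, apical margin rounded|flat_apex_straight:flat or slightly convex, apical margin almost straight
#character: id=mandibles	kind=categorical	name=Mandibles	weight=2	group=head	states=short_2x_labrum:shorter, ca. 2x as long as labrum|long_over_2_5x_labrum:longer, > 2.5x as long as labrum
#character: id=pronotum_hind_angles	kind=categorical	name=Pronotum hind angles	weight=2	group=pronotum	states=rectangular:ca. rectangular, sometimes produced in sharp denticle|rounded_or_obtuse:entirely rounded or obtuse
#character: id=pronotum_lateral_margin	kind=categorical	name=Pronotum lateral margin	weight=2	group=pronotum	states=continuously_rounded:continuously rounded between maximum width and hind angles|straight:straight from maximum width towards hind angles|slightly_concave:slightly concave from maximum width towards hind angles
#character: id=pronotum_proportion	kind=categorical	name=Pronotum proportion (width/length)	weight=2	group=pronotum	states=about_as_long_as_wide:about as long as wide (<= 1.1x)|slightly_wider:slightly wider than long (1.1-1.2x)|moderately_wider:moderately wider than long (1.2-1.3x)|clearly_wider:clearly wider than long (> 1.3x)
#character: id=pronotum_punctation	kind=categorical	name=Pronotum punctation	weight=2	group=pronotum	states=strong:strong|weak:weak
#character: id=hairs_upperside	kind=categorical	name=Hairs on upper side (pronotum, elytra)	weight=2	group=habitus	states=present:numerous hairs present|absent:without hairs, only regular setae
#character: id=setiferous_punctures_3rd_interval	kind=numerical	name=3rd elytral interval, number of setiferous punctures	weight=2	group=elytra	units=count
#character: id=stria5_apical_depression	kind=categorical	name=5th elytral stria and adjacent intervals (apical third)	weight=2	group=elytra	states=depressed:depressed|not_depressed:not depressed
#character: id=elytra_apical_margin	kind=categorical	name=Apical margin of elytra	weight=2	group=elytra	states=evenly_rounded:evenly rounded|sinuous_with_tooth:sinuous, with small tooth at end of suture
#character: id=mentum_tooth	kind=categorical	name=Mentum tooth	weight=2	group=head	states=present:with tooth|absent:without tooth
"taxon_id","name","in_region","body_length","coloration_upperside","metallic_luster","coloration_legs","first_antennomere","labrum","mandibles","pronotum_hind_angles","pronotum_lateral_margin","pronotum_proportion","pronotum_punctation","hairs_upperside","setiferous_punctures_3rd_interval","stria5_apical_depression","elytra_apical_margin","mentum_tooth"
"atranus_ruficollis","Atranus ruficollis",TRUE,"5.5..8","reddish_brown|dark_brown","?","?","?","?","?","rounded_or_obtuse","?","about_as_long_as_wide","strong","present","?","?","evenly_rounded","?"
"orthotrichus_cymindoides","Orthotrichus cymindoides",TRUE,"9..12","dark_brown_reddish_margins","?","reddish_brown","?","?","?","rounded_or_obtuse","?","clearly_wider","?","present","?","?","sinuous_with_tooth","?"
"olisthopus_fuscatus","Olisthopus fuscatus",TRUE,"5..6.5","?","?","?","?","convex_apex_rounded","short_2x_labrum","?","?","moderately_wider|clearly_wider","strong","absent","2..4","depressed|not_depressed","?","absent"
"olisthopus_glabricollis","Olisthopus glabricollis",TRUE,"5..6.5","?","?","?","?","convex_apex_rounded","short_2x_labrum","?","?","slightly_wider|moderately_wider","weak","absent","2..4","not_depressed","?","absent"
"anchomenus_dorsalis_infuscatus","Anchomenus dorsalis infuscatus",TRUE,"5..7","forebody_green_elytra_matt_brown","vivid","?","?","flat_apex_straight","long_over_2_5x_labrum","rectangular","?","?","?","absent","2..4","?","?","present"
"anchomenus_alcedo","Anchomenus alcedo",TRUE,"9..10.5","blue_to_violet","vivid","?","trumpet_shaped","flat_apex_straight","long_over_2_5x_labrum","rectangular","?","moderately_wider|clearly_wider","?","absent","2..4","?","?","present"
"anchomenus_bellus","Anchomenus bellus",FALSE,"8.7..10.3","blue_to_violet","vivid","?","regular","flat_apex_straight","long_over_2_5x_labrum","rectangular","?","slightly_wider|moderately_wider","?","absent","2..4","?","?","present"
"agonum_marginatum","Agonum marginatum",TRUE,"8.5..10.5","green_coppery_yellow_margin","?","?","?","flat_apex_straight","long_over_2_5x_labrum","rounded_or_obtuse","?","?","?","absent","2..4","?","?","present"
"agonum_viridicupreum","Agonum viridicupreum",TRUE,"8..10","elytra_green_forebody_reddish_coppery|black","vivid","?","?","flat_apex_straight","long_over_2_5x_labrum","rounded_or_obtuse","?","?","?","absent","5..7","?","?","present"
"agonum_sordidum","Agonum sordidum",TRUE,"7..9.5","elytra_brownish","absent","pale_brown_tibiae_darker","?","flat_apex_straight","long_over_2_5x_labrum","rounded_or_obtuse","?","?","?","absent","2..4","?","?","present"
"agonum_rugicolle","Agonum rugicolle",TRUE,"8.5..11.5","vivid_metallic_green|bronze|black","vivid|absent","?","?","flat_apex_straight","long_over_2_5x_labrum","rounded_or_obtuse","?","clearly_wider","?","absent","2..4","depressed","?","present"
"agonum_nigrum","Agonum nigrum",TRUE,"7..8.5","dark_brown_to_black","absent","dark_tibiae_paler","?","flat_apex_straight","long_over_2_5x_labrum","rounded_or_obtuse","continuously_rounded","moderately_wider","?","absent","2..4","depressed|not_depressed","?","present"
"agonum_mesostictum","Agonum mesostictum",TRUE,"7.5..9","dark_brown_to_black","absent|faint","dark_tibiae_paler","?","flat_apex_straight","long_over_2_5x_labrum","rounded_or_obtuse","straight|slightly_concave","slightly_wider","?","absent","2..4","not_depressed","?","present"
"agonum_monachum_syriacum","Agonum monachum syriacum",TRUE,"8.5..9","brown_faint_green_luster","faint","brown","?","flat_apex_straight","long_over_2_5x_labrum","rounded_or_obtuse","straight","about_as_long_as_wide","?","absent","2..4","depressed","?","present"
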