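condition_label,code_prefix,note
chronic obstructive pulmonary disease,J44,ICD-10 chapter prefix chosen by the package authors; supply your own list to reproduce a specific study definition
chronic obstructive pulmonary disease,J43,emphysema
bronchitis,J20,acute bronchitis
bronchitis,J21,acute bronchiolitis
bronchitis,J40,bronchitis not specified as acute or chronic
bronchitis,J41,simple and mucopurulent chronic bronchitis
bronchitis,J42,unspecified chronic bronchitis
pneumonia,J12,viral pneumonia
pneumonia,J13,pneumococcal pneumonia
pneumonia,J14,H. influenzae pneumonia
pneumonia,J15,bacterial pneumonia
pneumonia,J16,pneumonia other organisms
pneumonia,J17,pneumonia in diseases classified elsewhere
pneumonia,J18,pneumonia organism unspecified
pneumonia,J69.0,aspiration pneumonia
congestive heart failure,I50,heart failure
congestive heart failure,I11.0,hypertensive heart disease with heart failure
dehydration,E86,volume depletion
urinary tract infection,N39.0,UTI site not specified
urinary tract infection,N30,cystitis
urinary tract infection,N10,acute pyelonephritis
anaemia,D50,iron deficiency anaemia
anaemia,D51,vitamin B12 deficiency anaemia
anaemia,D52,folate deficiency anaemia
anaemia,D53,other nutritional anaemias
anaemia,D64,other and unspecified anaemias
cellulitis,L03,cellulitis
cellulitis,L08,other local infections of skin
leg ulcers,L97,ulcer of lower limb
leg ulcers,I83.0,varicose veins with ulcer
leg ulcers,I83.2,varicose veins with ulcer and inflammation
collapse or syncope,R55,syncope and collapse
constipation,K59.0,constipation
influenza,J09,influenza identified zoonotic virus
influenza,J10,influenza identified seasonal virus
influenza,J11,influenza virus not identified
fall-related fracture,S02,fracture of skull and facial bones
fall-related fracture,S22,fracture of rib(s) sternum and thoracic spine
fall-related fracture,S32,fracture of lumbar spine and pelvis
fall-related fracture,S42,fracture of shoulder and upper arm
fall-related fracture,S52,fracture of forearm
fall-related fracture,S62,fracture at wrist and hand level
fall-related fracture,S72,fracture of femur
fall-related fracture,S82,fracture of lower leg
fall-related injury,W00,fall on same level involving ice and snow
fall-related injury,W01,fall on same level from slipping tripping and stumbling
fall-related injury,W05,fall involving wheelchair
fall-related injury,W06,fall involving bed
fall-related injury,W07,fall involving chair
fall-related injury,W08,fall involving other furniture
fall-related injury,W10,fall on and from stairs and steps
fall-related injury,W18,other fall on same level
fall-related injury,W19,unspecified fall
gastroenteritis,A09,infectious gastroenteritis and colitis
epilepsy or convulsions,R56,convulsions not elsewhere classified
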