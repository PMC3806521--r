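participant_id,cohort,e1,e2,e3c,e3p,e4,e5,e_ds,speed_var,lat_accel,brake_time,dist_collision,time_collision,moca,tmt_a,tmt_b,cdt,tug
P001,young,1,0,2,1,2,0,2,1.76507256315359,1.12200853294566,25.5393550695749,44.4793642338957,4.44559212926907,30,29.333174945094,67.5129201219683,7,5.53121229439662
P002,young,1,1,0,3,3,0,3,1.7846538871117,1.22141871186036,10.8276927491297,32.5392329580714,1.9086169891012,29,15.862852056063,40.5983833530893,7,6.47190905888519
P003,young,1,3,4,3,0,4,1,2.11543026263702,1.85978376070176,22.6613420034298,16.8919340299356,4.47804498441192,29,26.0796873892711,53.6426335842201,7,3.94492979841987
P004,young,1,4,2,0,1,1,1,1.65992589300405,1.26437278812871,15.9871714496728,43.9271068602336,2.57159075294709,29,16.9379499837299,64.1882712720677,7,5.09938225889166
P005,older_healthy,2,4,4,1,1,6,1,2.14434797819372,1.89360278886752,28.4127872460266,21.1268918690891,3.16253830802631,29,27.9937446589227,160.03212266518,5,6.70878477435846
P006,older_healthy,2,1,0,0,1,2,1,1.34947868937522,1.14263256158382,13.0152232239696,51.1248340267818,4.41149689582945,25,31.8757356084723,65.9898689428694,5,7.17087227101853
P007,older_healthy,0,1,5,2,1,1,1,1.04685103679813,1.32315589986991,10.4967649538117,24.7975590017585,2.92603814071361,28,29.2827550974164,81.1973938181379,7,1
P008,older_healthy,1,0,1,1,3,3,0,1.99584432104616,1.19502633381754,11.6891852592524,26.0689737470072,4.38019939151723,27,14.0025651433501,70.3153950897723,7,5.68908187994269
P009,older_healthy,1,4,3,2,3,1,1,1.76772739113688,1.76385282261175,19.3433049274118,27.6430022299654,4.55161406675659,27,20.6473078228493,71.0061762190918,7,5.13572861556526
P010,older_impaired,3,6,4,3,1,2,1,2.19957831299217,2.28576998190456,17.3796585082907,28.1428033533395,1.89612650811253,23,9.0839120474977,89.488089864327,4,1
P011,older_impaired,2,7,3,0,3,3,6,2.05250093499692,1.12288002954622,26.296760462249,13.0824887335509,2.13611654742133,24,30.0760805054845,131.776780659753,2,16.9143644316655
P012,older_impaired,4,1,3,6,5,4,3,2.36256300030753,2.00601163709743,17.2832525714324,32.7921311072902,2.42746467939613,22,37.492353127626,102.196618284245,1,10.9052119651849
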