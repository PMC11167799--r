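id,release_area,release_date,release_lat,release_lon,length_cm,sex,recovery_method,method_printed,drift_days,predated,stomach_days,max_depth_m,distance_recovered_km,liberty_days,liberty_censored,fate,max_distance_km,strategy,destination,note
A10903,EC,2014-11-04,50.621,-2.274,52,,fishery_trawl,Otter Trawl,,FALSE,,76,41,300,FALSE,Caught,138,intermediate,,
A10904,EC,2014-11-04,50.621,-2.274,44,,fishery_net,Gill Nets,,FALSE,,94,234,382,FALSE,Caught,374,long,NS,digit run 94234382 split 94|234|382
A10898,EC,2014-11-04,50.621,-2.274,52,,fishery_rod,Rod & line,,FALSE,,79,4,698,FALSE,Caught,268,long,,digit run 794698 split 79|4|698
A10913,EC,2014-11-04,50.621,-2.274,51,,fishery_rod,Rod & line,,FALSE,,49,16,46,FALSE,Caught,73,,,digit run 491646 split 49|16|46
A10892,EC,2014-11-05,50.688,-2.217,,,beached,Beached,202,FALSE,,42,188,24,FALSE,Prem,116,,,digit run 4218824 split 42|188|24; no printed length
A10906,EC,2014-11-05,50.688,-2.217,53,,beached,Beached,35,FALSE,,86,13,708,FALSE,Prem,263,long,,digit run 8613708 split 86|13|708
A10880,EC,2014-11-05,50.688,-2.217,55,,beached,Beached,135,TRUE,10.36,83,206,292,FALSE,Predated,109,intermediate,,
A10883,EC,2014-11-05,50.688,-2.217,47,,beached,Beached,701,FALSE,,107,283,787,TRUE,Unknown,419,long,CS,liberty printed > 787
A10893,EC,2014-11-05,50.688,-2.217,62,,fishery_longline,Long line,,FALSE,,,253,1097,FALSE,Caught,,,,strategy column printed 'Tag lost'
A10889,EC,2014-11-05,50.688,-2.217,48,,fishery_rod,Rod & line,,FALSE,,105,78,225,FALSE,Caught,106,intermediate,,digit run 10578225 split 105|78|225
A10881,EC,2014-11-26,50.768,-2.354,47,M,beached,Beached,134,FALSE,,103,155,678,FALSE,Prem,122,intermediate,,
A10930,EC,2014-11-27,50.591,-2.318,44,,market,Fish Market,,FALSE,,57,,34,FALSE,Caught,45,,,
A10943,EC,2014-11-27,50.591,-2.318,45,,beached,Beached,9,FALSE,,78,214,284,FALSE,Prem,379,long,NS,
A10950,EC,2014-11-27,50.768,-2.354,47,F,beached,Beached,356,FALSE,,,159,1120,FALSE,,,,,predation and fate cells blank; strategy column printed 'Error'
A10952,NS,2015-05-13,52.060,1.550,76,,beached,Beached,58,TRUE,0.84,57,537,397,FALSE,Predated,411,long,,
A10920,NS,2015-05-13,52.060,1.550,63,,fishery_trawl,Otter Trawl,,FALSE,,59,12,364,FALSE,Caught,45,short,,
A10932,NS,2015-05-13,52.060,1.550,58,,fishery_net,Gill Nets,,FALSE,,53,4,373,FALSE,Caught,45,short,,digit run 534373 split 53|4|373
A10941,NS,2015-05-13,52.060,1.550,65,,beached,Beached,807,TRUE,1.82,,819,617,FALSE,Predated,,,,strategy column printed 'Error'
A10978a,NS,2017-05-18,52.400,1.750,52,,beached,Beached,12,FALSE,,92,256,566,FALSE,CaughtDiscarded,152,intermediate,EC,duplicate printed ID A10978 disambiguated with suffix a
A10939,NS,2015-05-24,52.396,1.753,57,,fishery_net,Fixed Nets,,FALSE,,40,134,156,FALSE,Caught,73,,,
A10918,NS,2015-05-24,52.396,1.753,62,F,beached,Beached,81,FALSE,,95,84,748,FALSE,Prem,450,long,EC,digit run 9584748 split 95|84|748
A10947,NS,2015-05-24,52.396,1.753,52,,beached,Beached,2,FALSE,,116,451,330,FALSE,Prem,668,long,EC+CS,digit run 116451330 split 116|451|330
A10931,NS,2015-05-24,52.396,1.753,58,,fishery_longline,Long line,,FALSE,,57,2,368,FALSE,Caught,41,short,,digit run 572368 split 57|2|368
A10979,NS,2015-05-27,52.396,1.753,70,F,fishery_longline,Long line,,FALSE,,56,31,218,FALSE,Caught,21,short,,digit run 5631218 split 56|31|218
A109742,NS,2015-05-27,52.396,1.753,56,,market,Landed,,FALSE,,,,58,FALSE,Caught,,,,method printed 'London draw' (garbled) read as landed
A10978b,NS,2015-05-27,52.396,1.753,59,,beached,Beached,12,FALSE,,92,143,192,FALSE,,152,intermediate,EC,duplicate printed ID A10978 suffix b; fate cell absent in print
A10961,NS,2015-05-27,52.396,1.753,49,M,beached,Beached,120,FALSE,,,57,12,FALSE,Death,,,,digit run 5712 split 57|12
A10964,NS,2015-05-27,52.396,1.753,56,M,beached,Beached,128,FALSE,,50,571,800,FALSE,Prem,52,intermediate,,digit run 50571800 split 50|571|800
A10989,NS,2015-05-27,52.396,1.753,55,M,beached,Beached,72,FALSE,,76,503,728,FALSE,Prem,252,long,NS,digit run 76503728 split 76|503|728
A10974,NS,2015-05-27,52.396,1.753,56,,beached,Beached,34,FALSE,,,106,68,FALSE,Prem,,,,digit run 10668 split 106|68
A10958,NS,2015-05-27,52.396,1.753,57,,fishery_trawl,Otter trawl,,FALSE,,69,2,339,FALSE,Caught,533,long,EC,digit run 692339 split 69|2|339
A10988,NS,2015-05-27,52.396,1.753,60,,fishery_rod,Rod & line,,FALSE,,95,421,430,FALSE,Caught,387,long,EC+CS,digit run 95421430 split 95|421|430
A10991,NS,2015-05-27,52.396,1.753,61,,fishery_net,Gill Nets,,FALSE,,80,0,1435,FALSE,Caught,214,intermediate,EC,printed intermediate although 214 km exceeds the 200 km threshold
A12694,NS,2017-05-18,52.082,1.560,57,,unknown,Unknown,,FALSE,,,55,32,FALSE,Caught,,,,digit run 5532 split 55|32
A10963,NS,2015-05-27,52.396,1.753,56,F,beached,Beached,5,FALSE,,,376,75,FALSE,,,,,predation and fate cells blank; strategy column printed 'Error'; digit run 37675 split 376|75
A10955,NS,2017-05-19,52.070,1.513,53,,market,Landed,,FALSE,,,,55,FALSE,Caught,,,,
A13607,IS,2017-06-20,53.991,-3.025,70,,beached,Beached,15,FALSE,,,374,36,FALSE,Death,,,,strategy column printed 'Error'
A13578,IS,2017-06-20,53.991,-3.025,64,,beached,Beached,128,TRUE,1.59,,2,2,FALSE,Predated,,,,
A13573,IS,2017-06-20,54.058,-3.229,53,,fishery_net,Gill Nets,,FALSE,,141,6,57,FALSE,Caught,31,,,digit run 141657 split 141|6|57
A13592,IS,2017-06-21,53.991,-3.025,55,,beached,Beached,75,TRUE,0.68,,376,7,FALSE,Predated,,,,digit run 3767 split 376|7
A13602,IS,2017-06-18,54.020,-3.020,61,,fishery_rod,Rod & line,,FALSE,,141,8,415,FALSE,Caught,419,long,CS,digit run 1418415 split 141|8|415
A13601,IS,2018-07-16,54.237,-3.127,62,,fishery_net,Gill Nets,,FALSE,,,19,104,FALSE,Caught,,,,digit run 19104 split 19|104
A13623,IS,2017-06-21,54.031,-3.165,60,,fishery_rod,Rod & line,,FALSE,,95,0,293,FALSE,Caught,355,long,CS,digit run 950293 split 95|0|293
A13629,IS,2017-06-18,53.9833,-3.0166,75,,beached,Beached,310,FALSE,,115,248,630,TRUE,Prem,350,long,CS,predation cell blank; liberty printed > 630
A13624,IS,2017-06-18,53.9833,-3.0166,59,,fishery_rod,Rod & line,,FALSE,,125,0,736,FALSE,Caught,346,long,CS,digit run 1250736 split 125|0|736
A13618,IS,2017-06-21,54.0333,-3.1666,51,,beached,Beached,10,FALSE,,,8,18,FALSE,Death,,,,digit run 818 split 8|18
A13589,IS,2017-06-19,53.991,-3.025,67,,beached,Beached,169,TRUE,,,263,93,FALSE,,,,,predation flagged without stomach days; fate cell blank; excluded from fate counts; digit run 26393 split 263|93
A15274,IS,2018-07-18,54.1166,-3.0166,63,,beached,Beached,57,FALSE,,103,62,275,FALSE,Prem,283,long,CS,digit run 10362275 split 103|62|275
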