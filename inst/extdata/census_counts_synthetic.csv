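language,census_year,age_lo,count
large_growing,2001,0,555
large_growing,2001,5,525
large_growing,2001,10,550
large_growing,2001,15,520
large_growing,2001,20,495
large_growing,2001,25,525
large_growing,2001,30,465
large_growing,2001,35,405
large_growing,2001,40,320
large_growing,2001,45,305
large_growing,2001,50,330
large_growing,2001,55,285
large_growing,2001,60,205
large_growing,2001,65,170
large_growing,2001,70,180
large_growing,2001,75,130
large_growing,2001,80,100
large_growing,2001,85,50
large_growing,2001,90,30
large_growing,2001,95,15
large_growing,2001,100,0
large_growing,2006,0,500
large_growing,2006,5,560
large_growing,2006,10,505
large_growing,2006,15,515
large_growing,2006,20,460
large_growing,2006,25,465
large_growing,2006,30,415
large_growing,2006,35,420
large_growing,2006,40,380
large_growing,2006,45,310
large_growing,2006,50,370
large_growing,2006,55,315
large_growing,2006,60,320
large_growing,2006,65,200
large_growing,2006,70,175
large_growing,2006,75,145
large_growing,2006,80,110
large_growing,2006,85,55
large_growing,2006,90,30
large_growing,2006,95,5
large_growing,2006,100,0
large_growing,2011,0,540
large_growing,2011,5,590
large_growing,2011,10,560
large_growing,2011,15,465
large_growing,2011,20,500
large_growing,2011,25,450
large_growing,2011,30,475
large_growing,2011,35,440
large_growing,2011,40,365
large_growing,2011,45,340
large_growing,2011,50,365
large_growing,2011,55,320
large_growing,2011,60,305
large_growing,2011,65,285
large_growing,2011,70,195
large_growing,2011,75,135
large_growing,2011,80,125
large_growing,2011,85,60
large_growing,2011,90,30
large_growing,2011,95,15
large_growing,2011,100,0
large_growing,2016,0,570
large_growing,2016,5,570
large_growing,2016,10,700
large_growing,2016,15,545
large_growing,2016,20,580
large_growing,2016,25,440
large_growing,2016,30,520
large_growing,2016,35,505
large_growing,2016,40,420
large_growing,2016,45,430
large_growing,2016,50,380
large_growing,2016,55,295
large_growing,2016,60,265
large_growing,2016,65,280
large_growing,2016,70,270
large_growing,2016,75,170
large_growing,2016,80,100
large_growing,2016,85,75
large_growing,2016,90,35
large_growing,2016,95,15
large_growing,2016,100,0
large_growing,2021,0,615
large_growing,2021,5,590
large_growing,2021,10,555
large_growing,2021,15,545
large_growing,2021,20,535
large_growing,2021,25,555
large_growing,2021,30,525
large_growing,2021,35,465
large_growing,2021,40,410
large_growing,2021,45,430
large_growing,2021,50,460
large_growing,2021,55,380
large_growing,2021,60,345
large_growing,2021,65,300
large_growing,2021,70,245
large_growing,2021,75,230
large_growing,2021,80,115
large_growing,2021,85,85
large_growing,2021,90,35
large_growing,2021,95,15
large_growing,2021,100,0
tiny_near_dormant,2001,0,0
tiny_near_dormant,2001,5,5
tiny_near_dormant,2001,10,5
tiny_near_dormant,2001,15,5
tiny_near_dormant,2001,20,5
tiny_near_dormant,2001,25,5
tiny_near_dormant,2001,30,10
tiny_near_dormant,2001,35,10
tiny_near_dormant,2001,40,10
tiny_near_dormant,2001,45,10
tiny_near_dormant,2001,50,5
tiny_near_dormant,2001,55,5
tiny_near_dormant,2001,60,25
tiny_near_dormant,2001,65,10
tiny_near_dormant,2001,70,20
tiny_near_dormant,2001,75,20
tiny_near_dormant,2001,80,5
tiny_near_dormant,2001,85,0
tiny_near_dormant,2001,90,0
tiny_near_dormant,2001,95,0
tiny_near_dormant,2001,100,0
tiny_near_dormant,2006,0,0
tiny_near_dormant,2006,5,0
tiny_near_dormant,2006,10,0
tiny_near_dormant,2006,15,0
tiny_near_dormant,2006,20,5
tiny_near_dormant,2006,25,0
tiny_near_dormant,2006,30,0
tiny_near_dormant,2006,35,5
tiny_near_dormant,2006,40,10
tiny_near_dormant,2006,45,5
tiny_near_dormant,2006,50,5
tiny_near_dormant,2006,55,0
tiny_near_dormant,2006,60,5
tiny_near_dormant,2006,65,25
tiny_near_dormant,2006,70,5
tiny_near_dormant,2006,75,15
tiny_near_dormant,2006,80,5
tiny_near_dormant,2006,85,0
tiny_near_dormant,2006,90,5
tiny_near_dormant,2006,95,0
tiny_near_dormant,2006,100,0
tiny_near_dormant,2011,0,5
tiny_near_dormant,2011,5,0
tiny_near_dormant,2011,10,0
tiny_near_dormant,2011,15,5
tiny_near_dormant,2011,20,5
tiny_near_dormant,2011,25,0
tiny_near_dormant,2011,30,0
tiny_near_dormant,2011,35,5
tiny_near_dormant,2011,40,0
tiny_near_dormant,2011,45,5
tiny_near_dormant,2011,50,5
tiny_near_dormant,2011,55,10
tiny_near_dormant,2011,60,5
tiny_near_dormant,2011,65,5
tiny_near_dormant,2011,70,10
tiny_near_dormant,2011,75,10
tiny_near_dormant,2011,80,10
tiny_near_dormant,2011,85,5
tiny_near_dormant,2011,90,5
tiny_near_dormant,2011,95,0
tiny_near_dormant,2011,100,0
tiny_near_dormant,2016,0,0
tiny_near_dormant,2016,5,0
tiny_near_dormant,2016,10,0
tiny_near_dormant,2016,15,0
tiny_near_dormant,2016,20,5
tiny_near_dormant,2016,25,0
tiny_near_dormant,2016,30,0
tiny_near_dormant,2016,35,5
tiny_near_dormant,2016,40,0
tiny_near_dormant,2016,45,0
tiny_near_dormant,2016,50,5
tiny_near_dormant,2016,55,5
tiny_near_dormant,2016,60,5
tiny_near_dormant,2016,65,5
tiny_near_dormant,2016,70,5
tiny_near_dormant,2016,75,5
tiny_near_dormant,2016,80,5
tiny_near_dormant,2016,85,5
tiny_near_dormant,2016,90,5
tiny_near_dormant,2016,95,5
tiny_near_dormant,2016,100,0
tiny_near_dormant,2021,0,0
tiny_near_dormant,2021,5,0
tiny_near_dormant,2021,10,0
tiny_near_dormant,2021,15,0
tiny_near_dormant,2021,20,0
tiny_near_dormant,2021,25,0
tiny_near_dormant,2021,30,0
tiny_near_dormant,2021,35,5
tiny_near_dormant,2021,40,0
tiny_near_dormant,2021,45,0
tiny_near_dormant,2021,50,5
tiny_near_dormant,2021,55,0
tiny_near_dormant,2021,60,10
tiny_near_dormant,2021,65,5
tiny_near_dormant,2021,70,5
tiny_near_dormant,2021,75,0
tiny_near_dormant,2021,80,10
tiny_near_dormant,2021,85,5
tiny_near_dormant,2021,90,0
tiny_near_dormant,2021,95,5
tiny_near_dormant,2021,100,0
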